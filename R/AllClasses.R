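#' @include alleles.R
NULL

## Central S4 containers. Probabilities are doubles; validity tolerances
## reflect accumulation over short exact products (<= 1e-9 slack).

#' DriveParams: homing and maternal-effect probabilities
#'
#' Parameters of the homing-drive model: \code{x}, the probability that
#' germline homing (HDR) converts the wild-type homolog of a drive
#' heterozygote into a drive allele (failure, probability \code{1 - x},
#' leaves an NHEJ-resistant allele R); and \code{y}, the probability that
#' maternally deposited Cas9/gRNA mutates a given wild-type allele of the
#' zygote into the resistant allele R* when the mother carries the drive.
#'
#' @slot x Numeric in \[0, 1\]; germline homing success probability.
#' @slot y Numeric in \[0, 1\]; zygotic maternal-effect mutation
#'   probability per wild-type allele.
#' @aliases DriveParams-class
#' @exportClass DriveParams
setClass("DriveParams", representation(x = "numeric", y = "numeric"))

setValidity("DriveParams", function(object) {
  msg <- character()
  for (nm in c("x", "y")) {
    v <- slot(object, nm)
    if (length(v) != 1L || !is.finite(v))
      msg <- c(msg, sprintf("%s must be a single finite number", nm))
    else if (v < 0 || v > 1)
      msg <- c(msg, sprintf("%s must lie in [0, 1], got %g", nm, v))
  }
  if (length(msg)) msg else TRUE
})

#' Construct DriveParams
#'
#' @param x Germline homing success probability in \[0, 1\].
#' @param y Zygotic maternal-effect mutation probability in \[0, 1\].
#' @return A \linkS4class{DriveParams} object.
#' @examples
#' DriveParams(x = 0.95, y = 0.87)
#' @export
DriveParams <- function(x, y) new("DriveParams", x = x, y = y)

#' @describeIn DriveParams Homing probability accessor.
#' @param object,params A \code{DriveParams} object.
#' @export
homingRate <- function(params) params@x

#' @describeIn DriveParams Maternal-effect probability accessor.
#' @export
maternalRate <- function(params) params@y

setMethod("show", "DriveParams", function(object) {
  cat(sprintf("DriveParams: homing x = %g, maternal effect y = %g\n",
              object@x, object@y))
})

#' GenotypeDistribution: exact probabilities over unordered genotypes
#'
#' A probability distribution over unordered diploid genotypes at the
#' drive locus — the currency of all cross operations. Probabilities are
#' nonnegative and sum to one (within 1e-9; the enumeration is exact up
#' to double rounding).
#'
#' @slot probs Named numeric vector; names are canonical genotype strings.
#' @aliases GenotypeDistribution-class
#' @exportClass GenotypeDistribution
setClass("GenotypeDistribution", representation(probs = "numeric"))

setValidity("GenotypeDistribution", function(object) {
  p <- object@probs
  if (is.null(names(p)) || any(!nzchar(names(p))))
    return("probs must be a named vector of genotype probabilities")
  ok <- vapply(names(p), function(g)
    identical(canonicalGenotype(g), g), logical(1L))
  if (!all(ok))
    return(paste("non-canonical genotype name(s):",
                 paste(names(p)[!ok], collapse = ", ")))
  if (anyDuplicated(names(p))) return("duplicated genotype names")
  if (any(p < -1e-12)) return("negative probability")
  if (abs(sum(p) - 1) > 1e-9)
    return(sprintf("probabilities sum to %.12f, not 1", sum(p)))
  TRUE
})

#' Construct a GenotypeDistribution
#'
#' @param probs Named numeric vector of genotype probabilities; names may
#'   use any allele order and the \code{R*} alias — they are canonicalised
#'   and merged.
#' @return A \linkS4class{GenotypeDistribution}.
#' @examples
#' genotypeDistribution(c("GD/WT" = 0.975, "R/WT" = 0.025))
#' @export
genotypeDistribution <- function(probs) {
  nm <- vapply(names(probs), canonicalGenotype, character(1L))
  merged <- tapply(probs, nm, sum)
  p <- as.numeric(merged)
  names(p) <- names(merged)
  p <- p[order(match(names(p), .allGenotypes()))]
  new("GenotypeDistribution", probs = p)
}

#' @describeIn GenotypeDistribution Named probability vector accessor.
#' @param object,x A \code{GenotypeDistribution}.
#' @export
genotypeProbs <- function(x) x@probs

#' Probability of one genotype
#'
#' @param x A \linkS4class{GenotypeDistribution}.
#' @param genotype Genotype string (any allele order, \code{R*} allowed).
#' @return The probability (0 if the genotype is absent from the support).
#' @examples
#' d <- genotypeDistribution(c("GD/WT" = 0.975, "R/WT" = 0.025))
#' genotypeProb(d, "WT/R")
#' @export
genotypeProb <- function(x, genotype) {
  g <- canonicalGenotype(genotype)
  p <- x@probs[g]
  if (is.na(p)) 0 else unname(p)
}

#' Allele frequencies of a genotype distribution
#'
#' @param x A \linkS4class{GenotypeDistribution} (or named genotype
#'   frequency vector).
#' @return Named numeric vector over \code{GD, R, RSTAR, WT} summing to 1.
#' @examples
#' alleleFrequencies(genotypeDistribution(c("GD/WT" = 1)))
#' @export
alleleFrequencies <- function(x) {
  if (is(x, "GenotypeDistribution")) x <- x@probs
  .alleleMarginal(x)
}

setMethod("show", "GenotypeDistribution", function(object) {
  cat("GenotypeDistribution over", length(object@probs), "genotype(s)\n")
  df <- data.frame(genotype = .displayGenotype(names(object@probs)),
                   probability = unname(object@probs),
                   percentage = sprintf("%.4f%%", 100 * unname(object@probs)))
  print(df, row.names = FALSE)
})

#' MatingScheme: how each generation mates
#'
#' Either \code{backcross_to_wildtype} (every individual is mated to a
#' wild-type partner, as in a laboratory introgression series) or
#' \code{random_mating} (panmixia; mating pairs form by genotype-by-sex
#' frequency products).
#'
#' @slot kind \code{"backcross_to_wildtype"} or \code{"random_mating"}.
#' @slot releaseFraction Initial drive-carrier frequency for
#'   \code{random_mating} starts built by \code{\link{releaseState}};
#'   \code{NA} otherwise.
#' @aliases MatingScheme-class
#' @exportClass MatingScheme
setClass("MatingScheme",
         representation(kind = "character", releaseFraction = "numeric"))

setValidity("MatingScheme", function(object) {
  if (!(object@kind %in% c("backcross_to_wildtype", "random_mating")))
    return("kind must be 'backcross_to_wildtype' or 'random_mating'")
  rf <- object@releaseFraction
  if (!is.na(rf) && (rf < 0 || rf > 1))
    return("releaseFraction must lie in [0, 1]")
  TRUE
})

#' Construct a MatingScheme
#'
#' @param kind \code{"backcross_to_wildtype"} or \code{"random_mating"}.
#' @param releaseFraction Initial drive-carrier frequency (used by
#'   \code{\link{releaseState}}; \code{NA} for backcross schemes).
#' @return A \linkS4class{MatingScheme}.
#' @export
matingScheme <- function(kind = c("backcross_to_wildtype", "random_mating"),
                         releaseFraction = NA_real_) {
  kind <- match.arg(kind)
  new("MatingScheme", kind = kind, releaseFraction = as.numeric(releaseFraction))
}

setMethod("show", "MatingScheme", function(object) {
  cat("MatingScheme:", object@kind)
  if (!is.na(object@releaseFraction))
    cat(sprintf(" (release fraction %g)", object@releaseFraction))
  cat("\n")
})

#' PopulationState: genotype-by-sex frequencies at one generation
#'
#' Genotype frequencies within females and within males (each marginal
#' sums to 1; sexes are assumed equally frequent). Offspring sex is
#' assigned 1:1 independent of genotype, so the two marginals coincide
#' after one generation of any scheme, but sex-specific initial states
#' (e.g. a male-only drive release) are representable.
#'
#' @slot female Named numeric genotype frequencies among females.
#' @slot male Named numeric genotype frequencies among males.
#' @slot femaleFraction Fraction of the cohort that is female (0.5 after
#'   any generation of reproduction; 0 or 1 for single-sex founder
#'   cohorts in backcross designs).
#' @slot generation Integer generation index (0-based).
#' @aliases PopulationState-class
#' @exportClass PopulationState
setClass("PopulationState",
         representation(female = "numeric", male = "numeric",
                        femaleFraction = "numeric", generation = "integer"))

setValidity("PopulationState", function(object) {
  for (sx in c("female", "male")) {
    p <- slot(object, sx)
    if (is.null(names(p))) return(sprintf("%s frequencies must be named", sx))
    ok <- vapply(names(p), function(g)
      identical(canonicalGenotype(g), g), logical(1L))
    if (!all(ok)) return(sprintf("non-canonical genotype in %s", sx))
    if (any(p < -1e-12)) return(sprintf("negative frequency in %s", sx))
    if (abs(sum(p) - 1) > 1e-9)
      return(sprintf("%s frequencies sum to %.12f, not 1", sx, sum(p)))
  }
  ff <- object@femaleFraction
  if (length(ff) != 1L || !is.finite(ff) || ff < 0 || ff > 1)
    return("femaleFraction must lie in [0, 1]")
  if (object@generation < 0L) return("generation must be >= 0")
  TRUE
})

.canonicalFreq <- function(freq) {
  nm <- vapply(names(freq), canonicalGenotype, character(1L))
  merged <- tapply(freq, nm, sum)
  p <- as.numeric(merged); names(p) <- names(merged)
  p[order(match(names(p), .allGenotypes()))]
}

#' Construct a PopulationState
#'
#' @param female Named genotype frequency vector for females.
#' @param male Named genotype frequency vector for males; defaults to
#'   \code{female}.
#' @param femaleFraction Fraction of the cohort that is female (default
#'   0.5).
#' @param generation Generation index (default 0).
#' @return A \linkS4class{PopulationState}.
#' @examples
#' populationState(c("WT/WT" = 0.9, "GD/WT" = 0.1))
#' @export
populationState <- function(female, male = female, femaleFraction = 0.5,
                            generation = 0L) {
  new("PopulationState", female = .canonicalFreq(female),
      male = .canonicalFreq(male), femaleFraction = femaleFraction,
      generation = as.integer(generation))
}

#' Initial state for a drive release
#'
#' Builds the generation-0 state in which a fraction of one or both sexes
#' are drive heterozygotes (GD/WT) and the remainder wild type.
#'
#' @param releaseFraction Drive-carrier frequency within the released
#'   sex(es), in \[0, 1\].
#' @param sex \code{"both"}, \code{"male"} or \code{"female"}: which sex
#'   carries the release.
#' @return A \linkS4class{PopulationState}.
#' @examples
#' releaseState(0.1, sex = "male")
#' @export
releaseState <- function(releaseFraction, sex = c("both", "male", "female")) {
  sex <- match.arg(sex)
  stopifnot(is.finite(releaseFraction),
            releaseFraction >= 0, releaseFraction <= 1)
  rel <- c("GD/WT" = releaseFraction, "WT/WT" = 1 - releaseFraction)
  wt <- c("WT/WT" = 1)
  populationState(
    female = if (sex %in% c("both", "female")) rel else wt,
    male = if (sex %in% c("both", "male")) rel else wt)
}

#' Single-sex founder cohort for backcross designs
#'
#' Builds a generation-0 cohort consisting entirely of one genotype and
#' one sex, as in the drive-introduction pedigree where drive-
#' heterozygous males are outcrossed to wild-type females. Under
#' \code{\link{matingScheme}("backcross_to_wildtype")} each cohort
#' member is mated to an external wild-type partner of the opposite
#' sex.
#'
#' @param genotype Founder genotype (default \code{"GD/WT"}).
#' @param sex \code{"male"} or \code{"female"}.
#' @return A \linkS4class{PopulationState} with \code{femaleFraction}
#'   0 or 1.
#' @examples
#' founderCohort("GD/WT", sex = "male")
#' @export
founderCohort <- function(genotype = "GD/WT", sex = c("male", "female")) {
  sex <- match.arg(sex)
  g <- stats::setNames(1, canonicalGenotype(genotype))
  wt <- c("WT/WT" = 1)
  populationState(female = if (sex == "female") g else wt,
                  male = if (sex == "male") g else wt,
                  femaleFraction = if (sex == "female") 1 else 0)
}

setMethod("show", "PopulationState", function(object) {
  cat(sprintf("PopulationState (generation %d)\n", object@generation))
  gts <- union(names(object@female), names(object@male))
  df <- data.frame(genotype = .displayGenotype(gts),
                   female = object@female[gts], male = object@male[gts])
  df[is.na(df)] <- 0
  print(df, row.names = FALSE)
})

#' Trajectory: genotype and allele frequencies over generations
#'
#' The result of \code{\link{propagateDrive}} or
#' \code{\link{wrightFisherDrive}}: per-generation genotype frequencies
#' (sexes pooled) and the implied allele frequencies.
#'
#' @slot genotypeFreq Numeric matrix, generations x genotypes.
#' @slot alleleFreq Numeric matrix, generations x 4 alleles.
#' @slot popSize Population size per generation (\code{NA} for the
#'   deterministic, infinite-population recursion).
#' @slot seed RNG seed used (\code{NA} for deterministic runs).
#' @aliases Trajectory-class
#' @exportClass Trajectory
setClass("Trajectory",
         representation(genotypeFreq = "matrix", alleleFreq = "matrix",
                        popSize = "numeric", seed = "numeric"))

setValidity("Trajectory", function(object) {
  if (nrow(object@genotypeFreq) != nrow(object@alleleFreq))
    return("genotype and allele matrices must have equal row counts")
  if (any(abs(rowSums(object@genotypeFreq) - 1) > 1e-9))
    return("genotype frequencies must sum to 1 at every generation")
  if (any(abs(rowSums(object@alleleFreq) - 1) > 1e-9))
    return("allele frequencies must sum to 1 at every generation")
  TRUE
})

#' @describeIn Trajectory Genotype-frequency matrix (rows = generations).
#' @param object,x A \code{Trajectory}.
#' @export
genotypeTrajectory <- function(x) x@genotypeFreq

#' @describeIn Trajectory Allele-frequency matrix (rows = generations).
#' @export
alleleTrajectory <- function(x) x@alleleFreq

#' @describeIn Trajectory Number of generations stored (including
#'   generation 0).
#' @export
nGenerations <- function(x) nrow(x@genotypeFreq)

setMethod("show", "Trajectory", function(object) {
  cat(sprintf("Trajectory: %d generation(s), %s\n",
              nrow(object@genotypeFreq),
              if (is.na(object@popSize)) "deterministic"
              else sprintf("Wright-Fisher N = %g, seed = %g",
                           object@popSize, object@seed)))
  cat("final allele frequencies:\n")
  print(round(object@alleleFreq[nrow(object@alleleFreq), ], 6))
})
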
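#' @include AllClasses.R
NULL

## Exact single-cross calculator. Three mechanistic operators composed by
## full enumeration of discrete outcomes, no sampling:
##   1. germline homing in each drive-carrying parent,
##   2. Mendelian gamete formation (R* transmitted as R),
##   3. zygotic maternal effect when the mother carries the drive.

.checkProb <- function(p, name) {
  if (length(p) != 1L || !is.finite(p) || p < 0 || p > 1)
    stop(name, " must be a single probability in [0, 1], got ",
         paste(p, collapse = ","), call. = FALSE)
  p
}

## Enumerate independent per-allele events: each allele at position i in
## `alleles` maps to outcomes[[i]] (named prob vector of replacement
## alleles). Returns named prob vector over canonical genotypes.
.enumeratePair <- function(alleles, outcomes) {
  o1 <- outcomes[[1L]]; o2 <- outcomes[[2L]]
  probs <- as.vector(outer(o1, o2))
  labs <- as.vector(outer(names(o1), names(o2),
                          function(a, b) mapply(function(x, y)
                            canonicalGenotype(c(x, y)), a, b)))
  p <- tapply(probs, labs, sum)
  stats::setNames(as.numeric(p), names(p))
}

#' Germline homing operator
#'
#' Models homing (the mutagenic chain reaction step) in the germline of
#' one parent: if the parent carries at least one drive allele, each
#' wild-type allele is converted to the drive (GD) with probability
#' \code{x} via HDR, or to the NHEJ-resistant allele R with probability
#' \code{1 - x}. Resistant alleles (R, R*) are immune to further cutting.
#' Parents without a drive allele are returned unchanged.
#'
#' @param parent Genotype string (e.g. \code{"GD/WT"}).
#' @param x Homing success probability in \[0, 1\].
#' @return Named numeric vector: distribution over germline genotypes.
#' @examples
#' germlineConvert("GD/WT", x = 0.95)
#' @export
germlineConvert <- function(parent, x) {
  .checkProb(x, "x")
  al <- parseGenotype(parent)
  if (!.hasDrive(al))
    return(stats::setNames(1, canonicalGenotype(al)))
  outcomes <- lapply(al, function(a) {
    if (a == "WT") c(GD = x, R = 1 - x) else stats::setNames(1, a)
  })
  out <- .enumeratePair(al, outcomes)
  out[out > 0]
}

#' Mendelian gamete distribution
#'
#' Each allele of a germline genotype is transmitted with probability
#' 1/2. A maternally induced resistant allele R* is transmitted as R:
#' the two are genetically identical and the star only labels the
#' generation in which the mutation arose, so provenance resets at
#' meiosis.
#'
#' @param germline Genotype string, or a named numeric vector of germline
#'   genotype probabilities (e.g. the output of
#'   \code{\link{germlineConvert}}), in which case the gamete pool is the
#'   probability-weighted mixture.
#' @return Named numeric vector over alleles, summing to 1.
#' @examples
#' gameteDistribution("GD/R")
#' gameteDistribution(germlineConvert("GD/WT", 0.95))
#' @export
gameteDistribution <- function(germline) {
  if (is.character(germline))
    germline <- stats::setNames(1, canonicalGenotype(germline))
  out <- stats::setNames(numeric(4L), .ALLELES)
  for (i in seq_along(germline)) {
    al <- parseGenotype(names(germline)[i])
    al[al == "RSTAR"] <- "R"
    out[al[1L]] <- out[al[1L]] + germline[i] / 2
    out[al[2L]] <- out[al[2L]] + germline[i] / 2
  }
  out[out > 0]
}

#' Zygotic maternal-effect operator
#'
#' Mutation of the zygote's wild-type alleles by Cas9/gRNA deposited in
#' the egg. If the mother carries at least one drive allele, each
#' wild-type allele of the zygote is independently mutated to the
#' resistant allele R* with probability \code{y}; GD, R and R* alleles
#' are unaffected (their target sites are gone). If the mother lacks the
#' drive this is the identity.
#'
#' @param zygote Genotype string (allele order is irrelevant: the
#'   operator acts per wild-type allele).
#' @param motherHasDrive Logical: does the mother's own genome carry a
#'   drive allele?
#' @param y Per-allele mutation probability in \[0, 1\].
#' @return Named numeric vector: distribution over zygote genotypes.
#' @examples
#' maternalZygoticEffect("GD/WT", motherHasDrive = TRUE, y = 0.87)
#' maternalZygoticEffect("WT/WT", motherHasDrive = TRUE, y = 0.87)
#' @export
maternalZygoticEffect <- function(zygote, motherHasDrive, y) {
  .checkProb(y, "y")
  al <- parseGenotype(zygote)
  if (!isTRUE(motherHasDrive))
    return(stats::setNames(1, canonicalGenotype(al)))
  outcomes <- lapply(al, function(a) {
    if (a == "WT") c(RSTAR = y, WT = 1 - y) else stats::setNames(1, a)
  })
  out <- .enumeratePair(al, outcomes)
  out[out > 0]
}

#' Exact offspring distribution of a single cross
#'
#' Composes the three mechanistic operators by full enumeration: germline
#' homing in each parent, Mendelian gametes, zygote formation, and the
#' zygotic maternal effect (active iff the mother's genome carries a
#' drive allele). The result is exact — no sampling is involved.
#'
#' @param mother,father Parental genotype strings.
#' @param params A \linkS4class{DriveParams} object.
#' @return A \linkS4class{GenotypeDistribution} over offspring genotypes.
#' @examples
#' crossGenotypes("GD/WT", "WT/WT", DriveParams(x = 0.95, y = 0.87))
#' @export
crossGenotypes <- function(mother, father, params) {
  stopifnot(is(params, "DriveParams"))
  validObject(params)
  key <- paste(canonicalGenotype(mother), canonicalGenotype(father),
               format(params@x, digits = 17), format(params@y, digits = 17),
               sep = "|")
  hit <- .crossCache[[key]]
  if (!is.null(hit)) return(hit)
  momAl <- parseGenotype(mother)
  momGam <- gameteDistribution(germlineConvert(mother, params@x))
  dadGam <- gameteDistribution(germlineConvert(father, params@x))
  motherHasDrive <- .hasDrive(momAl)

  acc <- stats::setNames(numeric(0L), character(0L))
  for (i in seq_along(momGam)) for (j in seq_along(dadGam)) {
    w <- momGam[i] * dadGam[j]
    zyg <- canonicalGenotype(c(names(momGam)[i], names(dadGam)[j]))
    post <- maternalZygoticEffect(zyg, motherHasDrive, params@y) * w
    for (k in seq_along(post)) {
      g <- names(post)[k]
      acc[g] <- (if (g %in% names(acc)) acc[[g]] else 0) + post[[k]]
    }
  }
  out <- genotypeDistribution(acc)
  .crossCache[[key]] <- out
  out
}

## Memoisation for crossGenotypes: the enumeration is deterministic in
## (mother, father, x, y); dynamics re-request the same crosses every
## generation. Mother and father keep their key positions — the
## maternal effect breaks the symmetry.
.crossCache <- new.env(parent = emptyenv())
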
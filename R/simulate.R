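#' @include dynamics.R estimation.R
NULL

## Seeded generators with the statistical structure of the germline-
## transmission and somatic-mosaicism experiments. All are
## bit-reproducible given (spec, seed) and leave the caller's RNG state
## untouched.

#' Simulate progeny class counts for germline-transmission crosses
#'
#' Per cross, draws \code{n} scored offspring from the trinomial with
#' class probabilities \code{(1 - d, d (1 - h), d h)} for
#' (GAL4+, dGAL4, QF2+), where \code{d} is the true disruption rate and
#' \code{h} the true HDR fraction among disrupted.
#'
#' @param d,h Numeric vectors of true rates (recycled to equal length),
#'   each in \[0, 1\].
#' @param n Integer vector of scored offspring per cross (>= 1).
#' @param crossId Optional cross labels.
#' @param seed Integer seed.
#' @return Count data frame with columns \code{cross_id},
#'   \code{GAL4plus}, \code{dGAL4}, \code{QF2plus}.
#' @examples
#' simulateGermlineCounts(d = 0.872, h = 0, n = 413, seed = 1)
#' @export
simulateGermlineCounts <- function(d, h, n, crossId = NULL, seed) {
  m <- max(length(d), length(h), length(n))
  d <- rep_len(d, m); h <- rep_len(h, m); n <- rep_len(as.integer(n), m)
  if (any(!is.finite(d)) || any(d < 0 | d > 1) ||
      any(!is.finite(h)) || any(h < 0 | h > 1))
    stop("d and h must be probabilities in [0, 1]", call. = FALSE)
  if (any(is.na(n)) || any(n < 1))
    stop("n must be >= 1 per cross", call. = FALSE)
  if (is.null(crossId)) crossId <- paste0("cross", seq_len(m))
  .withSeed(seed, {
    counts <- vapply(seq_len(m), function(i)
      stats::rmultinom(1L, n[i],
                       c(1 - d[i], d[i] * (1 - h[i]), d[i] * h[i]))[, 1L],
      numeric(3L))
    data.frame(cross_id = as.character(crossId),
               GAL4plus = counts[1L, ], dGAL4 = counts[2L, ],
               QF2plus = counts[3L, ], stringsAsFactors = FALSE)
  })
}

#' Simulate per-brain labeled-cell counts
#'
#' Per brain and reporter channel, draws the number of labeled cells
#' among \code{nCells} (default 1e5, the approximate neuron count of an
#' adult fly brain). With \code{rho = 0} counts are binomial; with
#' \code{rho > 0} they are beta-binomial with the same mean and
#' intra-class correlation \code{rho}, modelling brain-to-brain
#' overdispersion (e.g. clonal editing early in embryogenesis).
#'
#' @param pIntact,pHdr Per-cell probabilities of intact GAL4 (GFP
#'   channel) and of the HDR knock-in (lacZ channel).
#' @param nBrains Number of brains.
#' @param nCells Cells per brain (default 1e5).
#' @param rho Beta-binomial intra-class correlation, >= 0 (0 = binomial).
#' @param seed Integer seed.
#' @return Data frame with columns \code{brain}, \code{gfp}, \code{lacz}.
#' @examples
#' simulateBrainCounts(pIntact = 0.000206, pHdr = 0.008, nBrains = 5,
#'                     seed = 1)
#' @export
simulateBrainCounts <- function(pIntact, pHdr, nBrains, nCells = 1e5,
                                rho = 0, seed) {
  for (p in list(pIntact, pHdr))
    if (!is.finite(p) || p < 0 || p > 1)
      stop("pIntact and pHdr must be probabilities in [0, 1]", call. = FALSE)
  if (!is.finite(rho) || rho < 0 || rho >= 1)
    stop("rho must lie in [0, 1)", call. = FALSE)
  if (!is.finite(nBrains) || nBrains < 1)
    stop("nBrains must be >= 1", call. = FALSE)
  nBrains <- as.integer(nBrains); nCells <- as.integer(nCells)
  drawChannel <- function(p) {
    if (p == 0) return(integer(nBrains))
    if (rho == 0) return(stats::rbinom(nBrains, nCells, p))
    a <- p * (1 - rho) / rho
    b <- (1 - p) * (1 - rho) / rho
    stats::rbinom(nBrains, nCells, stats::rbeta(nBrains, a, b))
  }
  .withSeed(seed, data.frame(brain = seq_len(nBrains),
                             gfp = drawChannel(pIntact),
                             lacz = drawChannel(pHdr)))
}

#' Simulate a finite cohort through a drive pedigree
#'
#' Finite-sample realisation of the drive dynamics: generation 0 is the
#' initial state realised exactly (rounded to counts); each later
#' generation samples \code{nPerGeneration} individuals multinomially
#' from the exact offspring distribution given the realised parental
#' frequencies, under the given mating scheme.
#'
#' @param params A \linkS4class{DriveParams}.
#' @param scheme A \linkS4class{MatingScheme}.
#' @param initial A \linkS4class{PopulationState}; defaults to the
#'   drive-introduction pedigree start: a cohort of GD/WT males, each
#'   outcrossed to wild-type females.
#' @param nPerGeneration Individuals sampled per generation.
#' @param generations Number of generations to sample.
#' @param seed Integer seed.
#' @return Long data frame: \code{generation}, \code{genotype},
#'   \code{count}.
#' @examples
#' simulateDriveCohort(DriveParams(0.95, 0.87),
#'                     matingScheme("backcross_to_wildtype"),
#'                     nPerGeneration = 1000, generations = 2, seed = 1)
#' @export
simulateDriveCohort <- function(params, scheme,
                                initial = founderCohort("GD/WT", "male"),
                                nPerGeneration, generations, seed) {
  stopifnot(is(params, "DriveParams"), is(scheme, "MatingScheme"),
            is(initial, "PopulationState"))
  if (!is.finite(nPerGeneration) || nPerGeneration < 2)
    stop("nPerGeneration must be >= 2", call. = FALSE)
  tr <- wrightFisherDrive(initial, scheme, params,
                          popSize = nPerGeneration,
                          generations = generations, seed = seed)
  gm <- genotypeTrajectory(tr)
  out <- data.frame(
    generation = rep(seq_len(nrow(gm)) - 1L, ncol(gm)),
    genotype = rep(colnames(gm), each = nrow(gm)),
    count = as.integer(round(as.vector(gm) * nPerGeneration)),
    stringsAsFactors = FALSE)
  out <- out[out$count > 0, ]
  out[order(out$generation, match(out$genotype, .allGenotypes())), ,
      drop = FALSE]
}
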
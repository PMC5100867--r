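#' @include pedigree.R
NULL

## Multi-generation drive dynamics. The deterministic recursion is the
## infinite-population limit; wrightFisherDrive is its finite-population
## multinomial counterpart.

## Offspring genotype distribution given the current state and scheme.
.offspringDistribution <- function(state, scheme, params) {
  fem <- state@female; mal <- state@male
  acc <- stats::setNames(numeric(0L), character(0L))
  add <- function(acc, probs, w) {
    if (w == 0) return(acc)
    for (k in seq_along(probs)) {
      nm <- names(probs)[k]
      acc[nm] <- (if (nm %in% names(acc)) acc[[nm]] else 0) + w * probs[[k]]
    }
    acc
  }
  if (scheme@kind == "backcross_to_wildtype") {
    ## every cohort member mated to an external wild-type partner of the
    ## opposite sex; sexes weighted by the cohort's female fraction
    ff <- state@femaleFraction
    if (ff > 0) for (g in names(fem))
      acc <- add(acc, genotypeProbs(crossGenotypes(g, "WT/WT", params)),
                 ff * fem[g])
    if (ff < 1) for (g in names(mal))
      acc <- add(acc, genotypeProbs(crossGenotypes("WT/WT", g, params)),
                 (1 - ff) * mal[g])
  } else {
    for (gm in names(fem)) for (gf in names(mal))
      acc <- add(acc, genotypeProbs(crossGenotypes(gm, gf, params)),
                 fem[gm] * mal[gf])
  }
  genotypeProbs(genotypeDistribution(acc))
}

.pooledFreq <- function(state) {
  ff <- state@femaleFraction
  gts <- union(names(state@female), names(state@male))
  f <- stats::setNames(numeric(length(gts)), gts)
  f[names(state@female)] <- state@female * ff
  f[names(state@male)] <- f[names(state@male)] + state@male * (1 - ff)
  f
}

.buildTrajectory <- function(freqList, popSize = NA_real_, seed = NA_real_) {
  gts <- Reduce(union, lapply(freqList, names))
  gts <- gts[order(match(gts, .allGenotypes()))]
  gm <- t(vapply(freqList, function(f) {
    v <- stats::setNames(numeric(length(gts)), gts)
    v[names(f)] <- f
    v
  }, numeric(length(gts))))
  rownames(gm) <- paste0("G", seq_len(nrow(gm)) - 1L)
  am <- t(apply(gm, 1L, .alleleMarginal))
  new("Trajectory", genotypeFreq = gm, alleleFreq = am,
      popSize = popSize, seed = seed)
}

#' Deterministic multi-generation drive dynamics
#'
#' Propagates genotype frequencies through successive generations in the
#' infinite-population (deterministic) limit. Under
#' \code{random_mating}, the offspring distribution is the frequency-
#' weighted mixture of \code{\link{crossGenotypes}} over all
#' mother-by-father genotype pairs; under \code{backcross_to_wildtype},
#' every individual is mated to a wild-type partner. Offspring sex is
#' 1:1 independent of genotype.
#'
#' @param initial A \linkS4class{PopulationState} (see
#'   \code{\link{releaseState}}).
#' @param scheme A \linkS4class{MatingScheme}.
#' @param params A \linkS4class{DriveParams}.
#' @param generations Number of generations to advance (>= 0).
#' @return A \linkS4class{Trajectory} with \code{generations + 1} rows
#'   (generation 0 is the initial state, sexes pooled).
#' @examples
#' tr <- propagateDrive(releaseState(0.2), matingScheme("random_mating"),
#'                      DriveParams(0.95, 0.87), generations = 5)
#' alleleTrajectory(tr)
#' @export
propagateDrive <- function(initial, scheme, params, generations) {
  stopifnot(is(initial, "PopulationState"), is(scheme, "MatingScheme"),
            is(params, "DriveParams"))
  validObject(initial); validObject(scheme); validObject(params)
  generations <- as.integer(generations)
  if (is.na(generations) || generations < 0L)
    stop("generations must be a nonnegative integer", call. = FALSE)
  freqs <- vector("list", generations + 1L)
  freqs[[1L]] <- .pooledFreq(initial)
  state <- initial
  for (t in seq_len(generations)) {
    off <- .offspringDistribution(state, scheme, params)
    state <- populationState(off, off, generation = state@generation + 1L)
    freqs[[t + 1L]] <- off
  }
  .buildTrajectory(freqs)
}

## Evaluate expr with a private RNG stream; global .Random.seed untouched.
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

#' Wright-Fisher stochastic drive dynamics
#'
#' Finite-population counterpart of \code{\link{propagateDrive}}: each
#' generation, \code{popSize} offspring genotypes are drawn by a single
#' multinomial resampling step from the deterministic offspring
#' distribution given the current realised frequencies (simple
#' Wright-Fisher: non-overlapping generations, no age structure).
#' Reproducible given \code{seed}; the run owns a private RNG stream and
#' does not disturb the caller's random state.
#'
#' @inheritParams propagateDrive
#' @param popSize Population size per generation (>= 2).
#' @param seed Integer seed.
#' @return A \linkS4class{Trajectory}.
#' @examples
#' wrightFisherDrive(releaseState(0.2), matingScheme("random_mating"),
#'                   DriveParams(0.95, 0.87), popSize = 1000,
#'                   generations = 3, seed = 1)
#' @export
wrightFisherDrive <- function(initial, scheme, params, popSize, generations,
                              seed) {
  stopifnot(is(initial, "PopulationState"), is(scheme, "MatingScheme"),
            is(params, "DriveParams"))
  validObject(initial); validObject(scheme); validObject(params)
  if (!is.finite(popSize) || popSize < 2)
    stop("popSize must be >= 2", call. = FALSE)
  popSize <- as.integer(popSize)
  generations <- as.integer(generations)
  if (is.na(generations) || generations < 0L)
    stop("generations must be a nonnegative integer", call. = FALSE)
  .withSeed(seed, {
    freqs <- vector("list", generations + 1L)
    freqs[[1L]] <- .pooledFreq(initial)
    state <- initial
    for (t in seq_len(generations)) {
      off <- .offspringDistribution(state, scheme, params)
      counts <- stats::rmultinom(1L, popSize, off)[, 1L]
      real <- counts / popSize
      real <- real[real > 0]
      state <- populationState(real, real,
                               generation = state@generation + 1L)
      freqs[[t + 1L]] <- stats::setNames(
        as.numeric(counts), names(off))[counts > 0] / popSize
    }
    .buildTrajectory(freqs, popSize = popSize, seed = seed)
  })
}
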
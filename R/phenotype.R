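#' @include AllClasses.R
NULL

## Dual-reporter readout of the targeted GAL4 locus. Each allele copy of
## the locus is in one of three states: intact GAL4 (drives a UAS-GFP
## reporter), disrupted GAL4 after NHEJ (dGAL4, drives neither reporter),
## or an HDR knock-in of QF2 (drives a QUAS-lacZ reporter). Reporter
## state equals genetic state (no perdurance or threshold effects).

.LOCUS_STATES <- c("GAL4_INTACT", "DGAL4", "QF2_KNOCKIN")
.PROGENY_CLASSES <- c(GAL4_INTACT = "GAL4+", DGAL4 = "dGAL4",
                      QF2_KNOCKIN = "QF2+")

.checkLocusStates <- function(states) {
  states <- toupper(states)
  bad <- !(states %in% .LOCUS_STATES)
  if (any(bad))
    stop("unknown locus state(s): ", paste(unique(states[bad]), collapse = ", "),
         " (expected GAL4_INTACT, DGAL4, QF2_KNOCKIN)", call. = FALSE)
  states
}

#' Dual-reporter readout of a cell or animal
#'
#' Maps the set of GAL4-locus allele states present in a cell (one entry
#' per GAL4-bearing allele) to the two-channel reporter readout: GFP is
#' on iff any allele retains intact GAL4, lacZ is on iff any allele
#' carries the QF2 knock-in; a disrupted locus (dGAL4) alone drives
#' neither.
#'
#' @param states Character vector of locus states (nonempty), from
#'   \code{GAL4_INTACT}, \code{DGAL4}, \code{QF2_KNOCKIN}.
#' @return Named logical vector \code{c(gfp = ..., lacz = ...)}.
#' @examples
#' reporterReadout("GAL4_INTACT")
#' reporterReadout(c("DGAL4", "QF2_KNOCKIN"))
#' @export
reporterReadout <- function(states) {
  if (length(states) == 0L)
    stop("states must contain at least one locus state", call. = FALSE)
  states <- .checkLocusStates(states)
  c(gfp = "GAL4_INTACT" %in% states, lacz = "QF2_KNOCKIN" %in% states)
}

#' Classify a transmitted allele into a progeny class
#'
#' In the germline-transmission assay, each scored offspring inherits a
#' single GAL4-bearing chromosome from its father; the state of that one
#' allele defines the progeny class used in count tables.
#'
#' @param locus Character vector of locus states.
#' @return Factor with levels \code{GAL4+}, \code{dGAL4}, \code{QF2+}.
#' @examples
#' classifyProgeny(c("GAL4_INTACT", "DGAL4", "QF2_KNOCKIN"))
#' @export
classifyProgeny <- function(locus) {
  locus <- .checkLocusStates(locus)
  factor(unname(.PROGENY_CLASSES[locus]), levels = unname(.PROGENY_CLASSES))
}

#' Expected labeled-cell counts under somatic mosaicism
#'
#' Under per-cell independent editing of the GAL4 locus, the expected
#' number of GFP-positive cells is \code{pIntact * nCells} and of
#' lacZ-positive cells \code{pHdr * nCells}. The default \code{nCells}
#' is the approximate neuron count of an adult fly brain.
#'
#' @param pIntact Per-cell probability that GAL4 remains intact.
#' @param pHdr Per-cell probability of an HDR (QF2 knock-in) event.
#' @param pNhej Per-cell probability of NHEJ disruption; defaults to the
#'   complement. The three must sum to 1.
#' @param nCells Number of cells in the tissue (default 1e5).
#' @return Named numeric vector \code{c(gfp = ..., lacz = ...)}.
#' @examples
#' expectedSomaticCounts(pIntact = 0.000206, pHdr = 0.008)
#' @export
expectedSomaticCounts <- function(pIntact, pHdr,
                                  pNhej = 1 - pIntact - pHdr,
                                  nCells = 1e5) {
  for (p in list(pIntact, pHdr, pNhej))
    if (!is.finite(p) || p < -1e-9 || p > 1)
      stop("rates must be probabilities in [0, 1]", call. = FALSE)
  if (abs(pIntact + pHdr + pNhej - 1) > 1e-9)
    stop("pIntact + pHdr + pNhej must equal 1", call. = FALSE)
  if (!is.finite(nCells) || nCells <= 0)
    stop("nCells must be positive", call. = FALSE)
  c(gfp = pIntact * nCells, lacz = pHdr * nCells)
}
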
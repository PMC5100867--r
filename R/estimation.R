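#' @include phenotype.R
NULL

## Trinomial estimation from progeny class counts. Each scored offspring
## falls in one of three classes (GAL4+, dGAL4, QF2+); the quantities of
## interest are the total disruption rate d = P(not GAL4+) and the HDR
## fraction among disrupted h = P(QF2+ | disrupted). Intervals are
## Wilson score (Wald degenerates near d = 1 at the observed sample
## sizes); differences use Newcombe's score-based method. The package
## reports intervals, not p-values.

#' Wilson score interval for a binomial proportion
#'
#' @param k Number of successes (vectorised).
#' @param n Number of trials.
#' @param level Confidence level (default 0.95).
#' @return Matrix with columns \code{lower}, \code{upper}, clipped to
#'   \[0, 1\]; always contains the point estimate \code{k/n}.
#' @examples
#' wilsonInterval(360, 413)
#' @export
wilsonInterval <- function(k, n, level = 0.95) {
  stopifnot(all(n >= 1), all(k >= 0), all(k <= n),
            level > 0, level < 1)
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- k / n
  c2 <- z^2 / n
  centre <- (p + c2 / 2) / (1 + c2)
  half <- z * sqrt(p * (1 - p) / n + c2 / (4 * n)) / (1 + c2)
  lower <- pmax(0, centre - half)
  upper <- pmin(1, centre + half)
  ## at the boundaries centre and half coincide algebraically; pin the
  ## limit exactly rather than leaving double-rounding fuzz
  lower[k == 0] <- 0
  upper[k == n] <- 1
  cbind(lower = lower, upper = upper)
}

.checkCountRow <- function(counts) {
  need <- c("GAL4plus", "dGAL4", "QF2plus")
  miss <- setdiff(need, names(counts))
  if (length(miss))
    stop("count table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  for (cl in need) {
    v <- counts[[cl]]
    if (any(!is.finite(v)) || any(v < 0) || any(v != round(v)))
      stop("column ", cl, " must contain nonnegative integers", call. = FALSE)
  }
  counts
}

#' Estimate disruption rate and HDR fraction from progeny counts
#'
#' Maximum-likelihood trinomial estimation per cross:
#' \code{d = (dGAL4 + QF2plus) / n} (total disruption rate) and
#' \code{h = QF2plus / (dGAL4 + QF2plus)} (HDR fraction among
#' disrupted; defined as 0 with a degenerate-interval flag when no
#' disrupted offspring were observed). Both get Wilson score intervals.
#'
#' @param counts Data frame with columns \code{GAL4plus}, \code{dGAL4},
#'   \code{QF2plus} and optionally \code{cross_id} (one row per cross).
#' @param level Confidence level (default 0.95).
#' @return Data frame with one row per cross: \code{cross_id}, \code{n},
#'   \code{d}, \code{d_lower}, \code{d_upper}, \code{h}, \code{h_lower},
#'   \code{h_upper}, \code{h_degenerate}.
#' @examples
#' fitTrinomial(data.frame(GAL4plus = 53, dGAL4 = 360, QF2plus = 0))
#' @export
fitTrinomial <- function(counts, level = 0.95) {
  counts <- .checkCountRow(as.data.frame(counts))
  n <- counts$GAL4plus + counts$dGAL4 + counts$QF2plus
  if (any(n < 1))
    stop("each fitted row needs at least one scored offspring", call. = FALSE)
  disrupted <- counts$dGAL4 + counts$QF2plus
  d <- disrupted / n
  ciD <- wilsonInterval(disrupted, n, level)
  h <- ifelse(disrupted > 0, counts$QF2plus / pmax(disrupted, 1), 0)
  ciH <- matrix(0, nrow = length(n), ncol = 2,
                dimnames = list(NULL, c("lower", "upper")))
  pos <- disrupted > 0
  if (any(pos))
    ciH[pos, ] <- wilsonInterval(counts$QF2plus[pos], disrupted[pos], level)
  data.frame(
    cross_id = if (is.null(counts$cross_id))
      paste0("cross", seq_along(n)) else as.character(counts$cross_id),
    n = n, d = d, d_lower = ciD[, "lower"], d_upper = ciD[, "upper"],
    h = h, h_lower = ciH[, "lower"], h_upper = ciH[, "upper"],
    h_degenerate = !pos, stringsAsFactors = FALSE, row.names = NULL)
}

#' Estimate the maternal-effect germline mutation rate
#'
#' For the cross whose progeny carry neither genomic Cas9 nor gRNA but
#' whose mother carried both, the disruption rate of the transmitted
#' allele estimates the maternal-effect germline mutation rate — the
#' quantity the drive model calls \code{y}. This is
#' \code{\link{fitTrinomial}}'s \code{d} for that single row.
#'
#' @param counts One-row count data frame (see \code{\link{fitTrinomial}}).
#' @param level Confidence level.
#' @return List with \code{estimate}, \code{lower}, \code{upper},
#'   \code{n}.
#' @examples
#' estimateMaternalRate(data.frame(GAL4plus = 53, dGAL4 = 360, QF2plus = 0))
#' @export
estimateMaternalRate <- function(counts, level = 0.95) {
  counts <- as.data.frame(counts)
  if (nrow(counts) != 1L)
    stop("expected a single count row (one cross)", call. = FALSE)
  fit <- fitTrinomial(counts, level)
  list(estimate = fit$d, lower = fit$d_lower, upper = fit$d_upper, n = fit$n)
}

#' Difference in disruption rates between two crosses
#'
#' Point difference of the two disruption-rate estimates with a
#' Newcombe score-based (method 10) confidence interval built from the
#' per-cross Wilson bounds. An interval is reported instead of a test
#' verdict.
#'
#' @param rowA,rowB One-row count data frames.
#' @param level Confidence level.
#' @return List with \code{difference} (\code{d_A - d_B}), \code{lower},
#'   \code{upper}.
#' @examples
#' a <- data.frame(GAL4plus = 6, dGAL4 = 184, QF2plus = 10)
#' b <- data.frame(GAL4plus = 16, dGAL4 = 184, QF2plus = 0)
#' compareRates(a, b)
#' @export
compareRates <- function(rowA, rowB, level = 0.95) {
  fa <- fitTrinomial(as.data.frame(rowA), level)
  fb <- fitTrinomial(as.data.frame(rowB), level)
  if (nrow(fa) != 1L || nrow(fb) != 1L)
    stop("compareRates expects one row per cross", call. = FALSE)
  diff <- fa$d - fb$d
  lower <- diff - sqrt((fa$d - fa$d_lower)^2 + (fb$d_upper - fb$d)^2)
  upper <- diff + sqrt((fa$d_upper - fa$d)^2 + (fb$d - fb$d_lower)^2)
  list(difference = diff, lower = max(-1, lower), upper = min(1, upper))
}
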
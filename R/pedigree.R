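#' @include cross.R
NULL

#' G2 distribution of the two-generation backcross pedigree
#'
#' Enumerates the canonical drive-introduction pedigree exactly:
#' generation G0 is a drive-heterozygous (GD/WT) male crossed to a
#' wild-type female; G1 offspring are assigned a 1:1 sex ratio
#' independent of genotype, and every G1 individual is backcrossed to a
#' wild-type partner. The zygotic maternal effect acts only in the
#' broods of G1 \emph{female} drive carriers (the G0 mother is wild type,
#' so no G1 zygote is exposed). The returned distribution is the pooled
#' G2 offspring distribution, with equal brood sizes for all G1 parents.
#'
#' With \code{x = 0.95} and \code{y = 0.87} the pooled G2 frequencies are
#' R/WT = 0.026271875 (2.6\%) and R/R* = 0.010603125 (1.06\%) with the
#' maternal effect active, and R/WT = 0.036875 (3.7\%), R/R* = 0 with it
#' switched off. The off-case heterozygote frequency equals the on-case
#' sum R/WT + R/R*: the maternal effect converts part of the heterozygote
#' flow into homozygous resistants rather than creating resistance
#' \emph{de novo} in this pedigree.
#'
#' @param params A \linkS4class{DriveParams} object.
#' @param maternalEffect Logical; if \code{FALSE} the zygotic
#'   maternal-effect probability is forced to zero throughout (the
#'   germline homing probability \code{x} is unchanged).
#' @return A \linkS4class{GenotypeDistribution} over G2 genotypes.
#' @examples
#' pedigreeG2(DriveParams(0.95, 0.87))
#' pedigreeG2(DriveParams(0.95, 0.87), maternalEffect = FALSE)
#' @export
pedigreeG2 <- function(params, maternalEffect = TRUE) {
  stopifnot(is(params, "DriveParams"))
  eff <- if (maternalEffect) params else DriveParams(params@x, 0)
  g1 <- genotypeProbs(crossGenotypes("WT/WT", "GD/WT", eff))
  acc <- stats::setNames(numeric(0L), character(0L))
  for (i in seq_along(g1)) {
    g <- names(g1)[i]
    asFather <- genotypeProbs(crossGenotypes("WT/WT", g, eff))
    asMother <- genotypeProbs(crossGenotypes(g, "WT/WT", eff))
    for (part in list(asFather, asMother)) {
      w <- g1[i] / 2
      for (k in seq_along(part)) {
        nm <- names(part)[k]
        acc[nm] <- (if (nm %in% names(acc)) acc[[nm]] else 0) + w * part[[k]]
      }
    }
  }
  genotypeDistribution(acc)
}
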
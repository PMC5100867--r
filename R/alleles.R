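## Allele algebra for a single-locus homing drive.
##
## Four allele states:
##   WT    - wild type, cleavable target site
##   GD    - gene-drive cassette (Cas9 + gRNA) inserted at the locus
##   R     - resistant allele created by NHEJ after failed homing
##   RSTAR - resistant allele created by the dominant maternal effect
##           (zygotic mutation by maternally deposited Cas9/gRNA)
## R and RSTAR are genetically identical (target site destroyed, no drive
## cargo); the star is a provenance label for the generation in which the
## mutation arose, and it resets to R at meiosis.

#' Allele states of the drive locus
#'
#' The four allele states recognised by the model, in canonical order.
#' \code{RSTAR} is displayed as \code{R*}; parsers accept either token.
#'
#' @return Character vector \code{c("GD", "R", "RSTAR", "WT")}.
#' @examples
#' alleleStates()
#' @export
alleleStates <- function() c("GD", "R", "RSTAR", "WT")

.ALLELES <- c("GD", "R", "RSTAR", "WT")

.parseAllele <- function(token) {
  token <- toupper(trimws(token))
  token[token == "R*"] <- "RSTAR"
  token[token == "+"] <- "WT"
  bad <- !(token %in% .ALLELES)
  if (any(bad))
    stop("unknown allele token(s): ", paste(unique(token[bad]), collapse = ", "),
         " (expected WT, GD, R, RSTAR/R*)", call. = FALSE)
  token
}

#' Parse a genotype string
#'
#' Parses \code{"GD/WT"}-style strings into an allele pair. Tokens are
#' \code{WT}, \code{GD}, \code{R} and \code{RSTAR} (alias \code{R*};
#' \code{+} is accepted for \code{WT}). The pair is unordered unless the
#' caller tracks parental origin itself.
#'
#' @param genotype Genotype string, two allele tokens joined by \code{"/"}.
#' @return Character vector of length 2.
#' @examples
#' parseGenotype("GD/WT")
#' parseGenotype("R/R*")
#' @export
parseGenotype <- function(genotype) {
  stopifnot(is.character(genotype), length(genotype) == 1L)
  parts <- strsplit(genotype, "/", fixed = TRUE)[[1L]]
  if (length(parts) != 2L)
    stop("genotype must be two allele tokens joined by '/': ", genotype,
         call. = FALSE)
  .parseAllele(parts)
}

#' Canonical unordered genotype label
#'
#' Collapses an allele pair to its canonical unordered string
#' (\code{GD < R < RSTAR < WT}), so that \code{WT/GD} and \code{GD/WT}
#' report identically.
#'
#' @param alleles Character vector of length 2 (allele tokens), or a
#'   genotype string.
#' @return Canonical genotype string such as \code{"GD/WT"}.
#' @examples
#' canonicalGenotype(c("WT", "GD"))
#' canonicalGenotype("WT/R*")
#' @export
canonicalGenotype <- function(alleles) {
  if (is.character(alleles) && length(alleles) == 1L)
    alleles <- parseGenotype(alleles)
  alleles <- .parseAllele(alleles)
  paste(alleles[order(match(alleles, .ALLELES))], collapse = "/")
}

## Display form: RSTAR rendered as R*.
.displayGenotype <- function(genotype) gsub("RSTAR", "R*", genotype, fixed = TRUE)

## All ten unordered diploid genotypes, canonical order.
.allGenotypes <- function() {
  idx <- which(upper.tri(diag(4), diag = TRUE), arr.ind = TRUE)
  apply(idx, 1L, function(ij)
    canonicalGenotype(c(.ALLELES[ij[1L]], .ALLELES[ij[2L]])))
}

.hasDrive <- function(alleles) "GD" %in% alleles

## Allele marginal of a named genotype-probability vector: each genotype
## contributes half of its frequency per allele copy.
.alleleMarginal <- function(probs) {
  out <- stats::setNames(numeric(4L), .ALLELES)
  for (i in seq_along(probs)) {
    al <- parseGenotype(names(probs)[i])
    out[al[1L]] <- out[al[1L]] + probs[i] / 2
    out[al[2L]] <- out[al[2L]] + probs[i] / 2
  }
  out
}
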
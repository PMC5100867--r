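#' @include simulate.R
NULL

#' Read a progeny count table
#'
#' Reads a CSV or TSV (delimiter inferred from the file extension;
#' anything not ending in \code{.tsv}/\code{.txt} is treated as CSV)
#' with columns \code{cross_id}, \code{GAL4plus}, \code{dGAL4},
#' \code{QF2plus}. \code{'#'}-prefixed lines are comments. Validation
#' errors name the offending row and column.
#'
#' @param path File path.
#' @return Validated count data frame.
#' @export
readCountTable <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                          stringsAsFactors = FALSE, check.names = FALSE)
  ## accept the display-form headers too
  names(df)[names(df) == "GAL4+"] <- "GAL4plus"
  names(df)[names(df) == "QF2+"] <- "QF2plus"
  need <- c("cross_id", "GAL4plus", "dGAL4", "QF2plus")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("count table ", path, " is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (nrow(df) == 0L)
    stop("count table ", path, " has a header but no rows", call. = FALSE)
  for (cl in c("GAL4plus", "dGAL4", "QF2plus")) {
    v <- suppressWarnings(as.numeric(df[[cl]]))
    bad <- which(!is.finite(v) | v < 0 | v != round(v))
    if (length(bad))
      stop(sprintf("count table %s: row %d, column %s must be a %s",
                   path, bad[1L], cl, "nonnegative integer"), call. = FALSE)
    df[[cl]] <- as.integer(v)
  }
  df[need]
}

#' Write a progeny count table
#'
#' @param counts Count data frame (see \code{\link{readCountTable}}).
#' @param path Output path; \code{.tsv}/\code{.txt} write tab-separated,
#'   otherwise comma-separated.
#' @return \code{path}, invisibly.
#' @export
writeCountTable <- function(counts, path) {
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(counts, path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

.provenanceHeader <- function(extra = character()) {
  c(sprintf("# matdrive %s",
            as.character(utils::packageVersion("matdrive"))),
    extra)
}

#' Write a genotype distribution as TSV
#'
#' Columns \code{genotype}, \code{probability}, \code{percentage},
#' preceded by a \code{'#'}-prefixed provenance header.
#'
#' @param x A \linkS4class{GenotypeDistribution}.
#' @param path Output path.
#' @param extraHeader Extra \code{'#'} header lines (e.g. the parameters
#'   and seed of the run).
#' @return \code{path}, invisibly.
#' @export
writeGenotypeTable <- function(x, path, extraHeader = character()) {
  stopifnot(is(x, "GenotypeDistribution"))
  p <- genotypeProbs(x)
  df <- data.frame(genotype = names(p), probability = unname(p),
                   percentage = 100 * unname(p))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(.provenanceHeader(extraHeader), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a genotype distribution written by \code{writeGenotypeTable}
#'
#' @param path File path.
#' @return A \linkS4class{GenotypeDistribution}.
#' @export
readGenotypeTable <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          comment.char = "#", stringsAsFactors = FALSE)
  genotypeDistribution(stats::setNames(df$probability, df$genotype))
}

#' Write a trajectory as TSV
#'
#' Long format: \code{generation}, \code{genotype}, \code{frequency},
#' with a \code{'#'} provenance header recording population size and
#' seed for stochastic runs.
#'
#' @param x A \linkS4class{Trajectory}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeTrajectoryTable <- function(x, path) {
  stopifnot(is(x, "Trajectory"))
  gm <- genotypeTrajectory(x)
  hdr <- if (is.na(x@popSize)) "# deterministic" else
    sprintf("# wright-fisher popSize=%g seed=%g", x@popSize, x@seed)
  df <- data.frame(generation = rep(seq_len(nrow(gm)) - 1L, ncol(gm)),
                   genotype = rep(colnames(gm), each = nrow(gm)),
                   frequency = as.vector(gm))
  df <- df[order(df$generation), ]
  con <- file(path, "w"); on.exit(close(con))
  writeLines(.provenanceHeader(hdr), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Monte-Carlo mechanistic cross simulator
#'
#' Independent per-individual sampling of the same mechanistic steps as
#' \code{\link{crossGenotypes}} — germline homing, Mendelian gamete
#' choice, zygotic maternal effect — used for cross-validating the exact
#' enumeration. It deliberately shares no enumeration code with
#' \code{crossGenotypes}.
#'
#' @param mother,father Parental genotype strings.
#' @param params A \linkS4class{DriveParams}.
#' @param n Number of simulated offspring.
#' @param seed Integer seed.
#' @return Named numeric vector of observed genotype fractions.
#' @examples
#' mcCross("GD/WT", "WT/WT", DriveParams(0.95, 0.87), n = 1e4, seed = 1)
#' @export
mcCross <- function(mother, father, params, n, seed) {
  stopifnot(is(params, "DriveParams"))
  momAl <- parseGenotype(mother); dadAl <- parseGenotype(father)
  n <- as.integer(n)
  .withSeed(seed, {
    germ <- function(al) {
      ## n x 2 matrix of germline alleles after homing
      m <- matrix(rep(al, each = n), nrow = n)
      if ("GD" %in% al) {
        for (j in 1:2) if (al[j] == "WT") {
          hdr <- stats::runif(n) < params@x
          m[, j] <- ifelse(hdr, "GD", "R")
        }
      }
      m
    }
    gamete <- function(m) {
      pick <- ifelse(stats::runif(n) < 0.5, 1L, 2L)
      g <- m[cbind(seq_len(n), pick)]
      ifelse(g == "RSTAR", "R", g)
    }
    momGam <- gamete(germ(momAl))
    dadGam <- gamete(germ(dadAl))
    zyg <- cbind(momGam, dadGam)
    if ("GD" %in% momAl) {
      for (j in 1:2) {
        hit <- zyg[, j] == "WT" & stats::runif(n) < params@y
        zyg[hit, j] <- "RSTAR"
      }
    }
    lab <- ifelse(match(zyg[, 1L], .ALLELES) <= match(zyg[, 2L], .ALLELES),
                  paste(zyg[, 1L], zyg[, 2L], sep = "/"),
                  paste(zyg[, 2L], zyg[, 1L], sep = "/"))
    tab <- table(lab)
    stats::setNames(as.numeric(tab), names(tab)) / n
  })
}

#' Worked-example report for the two-generation pedigree
#'
#' Runs \code{\link{pedigreeG2}} at the worked-example parameters
#' (default \code{x = 0.95}, \code{y = 0.87}) with the maternal effect
#' on and off, and juxtaposes the computed G2 frequencies of the
#' resistant genotype classes with the published summary percentages
#' (R/+ 2.6 vs 3.7, R/R* 1.06 vs 0) at their printed precision, with a
#' pass flag per value. Optionally appends a Monte-Carlo
#' cross-validation of the G1 cross via \code{\link{mcCross}}.
#'
#' @param outdir Optional directory; if given, writes
#'   \code{g2_summary.tsv} (and \code{mc_check.tsv} when
#'   \code{mcReps > 0}) there.
#' @param x,y Drive parameters.
#' @param mcReps Monte-Carlo offspring count for the cross-validation
#'   (0 to skip).
#' @param seed Seed for the Monte-Carlo check.
#' @return Data frame with columns \code{quantity}, \code{computed_pct},
#'   \code{reference_pct}, \code{digits}, \code{pass}; the Monte-Carlo
#'   summary (if any) is attached as attribute \code{"mc"}.
#' @examples
#' reproduceSummary()
#' @export
reproduceSummary <- function(outdir = NULL, x = 0.95, y = 0.87,
                             mcReps = 0, seed = 1) {
  on <- genotypeProbs(pedigreeG2(DriveParams(x, y), maternalEffect = TRUE))
  off <- genotypeProbs(pedigreeG2(DriveParams(x, y), maternalEffect = FALSE))
  get <- function(p, g) { v <- p[canonicalGenotype(g)]; if (is.na(v)) 0 else unname(v) }
  tbl <- data.frame(
    quantity = c("R/+ (maternal effect on)", "R/+ (maternal effect off)",
                 "R/R* (maternal effect on)", "R/R* (maternal effect off)"),
    computed_pct = 100 * c(get(on, "R/WT"), get(off, "R/WT"),
                           get(on, "R/RSTAR"), get(off, "R/RSTAR")),
    reference_pct = c(2.6, 3.7, 1.06, 0),
    digits = c(1L, 1L, 2L, 2L), stringsAsFactors = FALSE)
  tbl$pass <- round(tbl$computed_pct, tbl$digits) == tbl$reference_pct
  mc <- NULL
  if (mcReps > 0) {
    exact <- genotypeProbs(crossGenotypes("GD/WT", "WT/WT",
                                          DriveParams(x, y)))
    obs <- mcCross("GD/WT", "WT/WT", DriveParams(x, y), n = mcReps,
                   seed = seed)
    gts <- union(names(exact), names(obs))
    p <- stats::setNames(numeric(length(gts)), gts)
    p[names(exact)] <- exact
    o <- stats::setNames(numeric(length(gts)), gts)
    o[names(obs)] <- obs
    se <- sqrt(p * (1 - p) / mcReps)
    mc <- data.frame(genotype = gts, exact = unname(p), mc = unname(o),
                     se = unname(se),
                     within_3se = abs(unname(o - p)) <= 3 * unname(se) + 1e-12,
                     stringsAsFactors = FALSE)
  }
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(tbl, file.path(outdir, "g2_summary.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    if (!is.null(mc))
      utils::write.table(mc, file.path(outdir, "mc_check.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
  }
  attr(tbl, "mc") <- mc
  tbl
}
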
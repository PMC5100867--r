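# Independent oracles used across the suite.

# Brute-force per-individual Monte-Carlo cross simulator, written
# directly from the mechanistic description and sharing no code with
# crossGenotypes() or mcCross(): one offspring at a time, explicit
# sampling of each step.
oracleCross <- function(mother, father, x, y, n, seed) {
  set.seed(seed)
  canonical <- function(a, b) {
    ord <- c(GD = 1, R = 2, RSTAR = 3, WT = 4)
    if (ord[[a]] <= ord[[b]]) paste(a, b, sep = "/") else paste(b, a, sep = "/")
  }
  germline <- function(alleles) {
    if (!("GD" %in% alleles)) return(alleles)
    vapply(alleles, function(a) {
      if (a != "WT") a
      else if (stats::runif(1) < x) "GD" else "R"
    }, character(1))
  }
  momAl <- strsplit(mother, "/")[[1]]
  dadAl <- strsplit(father, "/")[[1]]
  out <- character(n)
  for (i in seq_len(n)) {
    mg <- sample(germline(momAl), 1)
    if (mg == "RSTAR") mg <- "R"
    dg <- sample(germline(dadAl), 1)
    if (dg == "RSTAR") dg <- "R"
    zyg <- c(mg, dg)
    if ("GD" %in% momAl)
      zyg <- vapply(zyg, function(a)
        if (a == "WT" && stats::runif(1) < y) "RSTAR" else a, character(1))
    out[i] <- canonical(zyg[1], zyg[2])
  }
  table(out) / n
}

# Exact (non-simulated) coverage of the Wilson interval at (n, p) by
# summation over the binomial outcome distribution.
exactWilsonCoverage <- function(n, p, level = 0.95) {
  k <- 0:n
  ci <- wilsonInterval(k, n, level)
  inside <- ci[, "lower"] <= p & p <= ci[, "upper"]
  sum(stats::dbinom(k[inside], n, p))
}

# Compare a GenotypeDistribution against observed Monte-Carlo fractions:
# TRUE iff every genotype (union of supports) agrees within `z` binomial
# standard errors at sample size n.
mcAgrees <- function(exact, observed, n, z = 3) {
  gts <- union(names(exact), names(observed))
  p <- setNames(numeric(length(gts)), gts); p[names(exact)] <- exact
  o <- setNames(numeric(length(gts)), gts); o[names(observed)] <- observed
  se <- sqrt(p * (1 - p) / n)
  all(abs(o - p) <= z * se + 1e-9)
}
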
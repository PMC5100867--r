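# Allele algebra and the three mechanistic operators.

test_that("genotype strings parse, canonicalise and reject junk", {
  expect_equal(parseGenotype("GD/WT"), c("GD", "WT"))
  expect_equal(canonicalGenotype("WT/GD"), "GD/WT")
  expect_equal(canonicalGenotype("WT/R*"), "RSTAR/WT")
  expect_equal(canonicalGenotype("R*/R"), "R/RSTAR")
  expect_error(parseGenotype("GD/WT/R"), "two allele tokens")
  expect_error(parseGenotype("GD/XX"), "unknown allele")
})

test_that("DriveParams validates its probabilities", {
  expect_s4_class(DriveParams(0.95, 0.87), "DriveParams")
  expect_equal(homingRate(DriveParams(0.3, 0.4)), 0.3)
  expect_equal(maternalRate(DriveParams(0.3, 0.4)), 0.4)
  expect_error(DriveParams(1.2, 0.5), "\\[0, 1\\]")
  expect_error(DriveParams(0.5, -0.1), "\\[0, 1\\]")
})

test_that("germline homing converts WT alleles only in drive carriers", {
  expect_equal(germlineConvert("GD/WT", 1), c("GD/GD" = 1))
  expect_equal(germlineConvert("GD/WT", 0.95),
               c("GD/GD" = 0.95, "GD/R" = 0.05))
  # no drive allele: identity at any x
  expect_equal(germlineConvert("R/WT", 0.3), c("R/WT" = 1))
  expect_equal(germlineConvert("WT/WT", 0.9), c("WT/WT" = 1))
  # resistant partner is immune to cutting
  expect_equal(germlineConvert("GD/R", 0.95), c("GD/R" = 1))
  expect_equal(germlineConvert("GD/RSTAR", 0.95), c("GD/RSTAR" = 1))
  expect_error(germlineConvert("GD/WT", 1.5), "x must be")
})

test_that("gametes are Mendelian and R* provenance resets at meiosis", {
  expect_equal(gameteDistribution("GD/GD"), c(GD = 1))
  expect_equal(gameteDistribution("GD/R"), c(GD = 0.5, R = 0.5))
  expect_equal(gameteDistribution("RSTAR/WT"), c(R = 0.5, WT = 0.5))
  # marginal gamete pool of a converted GD/WT germline: x + (1-x)/2, (1-x)/2
  pool <- gameteDistribution(germlineConvert("GD/WT", 0.95))
  expect_equal(pool, c(GD = 0.975, R = 0.025))
})

test_that("zygotic maternal effect hits each WT allele independently", {
  expect_equal(maternalZygoticEffect("GD/WT", FALSE, 0.9), c("GD/WT" = 1))
  expect_equal(maternalZygoticEffect("GD/WT", TRUE, 0.87),
               c("GD/RSTAR" = 0.87, "GD/WT" = 0.13))
  # two WT alleles: (1-y)^2, 2y(1-y), y^2
  out <- maternalZygoticEffect("WT/WT", TRUE, 0.87)
  expect_equal(out[["WT/WT"]], 0.0169)
  expect_equal(out[["RSTAR/WT"]], 0.2262)
  expect_equal(out[["RSTAR/RSTAR"]], 0.7569)
  # resistant and drive alleles untouched
  expect_equal(maternalZygoticEffect("GD/R", TRUE, 0.9), c("GD/R" = 1))
  expect_error(maternalZygoticEffect("GD/WT", TRUE, 2), "y must be")
})

params <- DriveParams(0.95, 0.87)

test_that("cross enumeration reproduces the worked single-cross examples", {
  expect_equal(genotypeProbs(crossGenotypes("WT/WT", "WT/WT", params)),
               c("WT/WT" = 1))
  # drive mother x wild-type father: maternal effect active
  d <- crossGenotypes("GD/WT", "WT/WT", params)
  expect_equal(genotypeProb(d, "GD/WT"), 0.12675)
  expect_equal(genotypeProb(d, "GD/R*"), 0.84825)
  expect_equal(genotypeProb(d, "R/WT"), 0.00325)
  expect_equal(genotypeProb(d, "R/R*"), 0.02175)
  # drive father x wild-type mother: no maternal effect at any y
  d2 <- crossGenotypes("WT/WT", "GD/WT", params)
  expect_equal(genotypeProbs(d2), c("GD/WT" = 0.975, "R/WT" = 0.025))
})

allG <- c("GD/GD", "GD/R", "R/R", "GD/RSTAR", "R/RSTAR", "RSTAR/RSTAR",
          "GD/WT", "R/WT", "RSTAR/WT", "WT/WT")

test_that("cross distributions sum to one over a parameter grid", {
  for (x in c(0, 0.3, 1)) for (y in c(0, 0.5, 1))
    for (m in allG) for (f in c("WT/WT", "GD/WT", "R/RSTAR")) {
      p <- genotypeProbs(crossGenotypes(m, f, DriveParams(x, y)))
      expect_lt(abs(sum(p) - 1), 1e-12)
      expect_true(all(p >= 0))
    }
})

test_that("y = 0 never produces an R* allele and makes crosses symmetric", {
  for (x in c(0, 0.4, 0.95, 1)) for (m in allG) for (f in allG) {
    pr <- DriveParams(x, 0)
    ab <- genotypeProbs(crossGenotypes(m, f, pr))
    expect_false(any(grepl("RSTAR", names(ab))))
    ba <- genotypeProbs(crossGenotypes(f, m, pr))
    expect_equal(ab, ba[names(ab)])
  }
})

test_that("perfect homing from a non-drive mother yields no resistance", {
  d <- crossGenotypes("WT/WT", "GD/WT", DriveParams(1, 0.87))
  expect_false(any(grepl("R", names(genotypeProbs(d)))))
})

test_that("exact enumeration matches the brute-force per-individual oracle", {
  cases <- list(c("GD/WT", "WT/WT", 0.95, 0.87),
                c("WT/WT", "GD/WT", 0.95, 0.87),
                c("GD/WT", "GD/WT", 0.7, 0.4),
                c("GD/RSTAR", "R/WT", 0.6, 0.9))
  n <- 2e4
  for (i in seq_along(cases)) {
    cs <- cases[[i]]
    x <- as.numeric(cs[3]); y <- as.numeric(cs[4])
    exact <- genotypeProbs(crossGenotypes(cs[1], cs[2], DriveParams(x, y)))
    obs <- oracleCross(cs[1], cs[2], x, y, n, seed = 100 + i)
    expect_true(mcAgrees(exact, obs, n), label = paste(cs, collapse = " "))
  }
})

test_that("packaged Monte-Carlo simulator agrees with enumeration and is seeded", {
  exact <- genotypeProbs(crossGenotypes("GD/WT", "WT/WT", params))
  obs <- mcCross("GD/WT", "WT/WT", params, n = 5e4, seed = 11)
  expect_true(mcAgrees(exact, obs, 5e4))
  expect_identical(obs, mcCross("GD/WT", "WT/WT", params, n = 5e4, seed = 11))
})
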
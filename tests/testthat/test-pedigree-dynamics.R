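# Two-generation pedigree enumeration and multi-generation dynamics.

params <- DriveParams(0.95, 0.87)

test_that("G2 pedigree reproduces the worked-example frequencies exactly", {
  on <- pedigreeG2(params, maternalEffect = TRUE)
  off <- pedigreeG2(params, maternalEffect = FALSE)
  # exact rational values of the enumeration
  expect_equal(genotypeProb(on, "R/WT"), 0.026271875)
  expect_equal(genotypeProb(on, "R/R*"), 0.010603125)
  expect_equal(genotypeProb(off, "R/WT"), 0.036875)
  expect_equal(genotypeProb(off, "R/R*"), 0)
  # printed precision: 2.6 / 3.7 / 1.06 / 0 percent
  expect_equal(round(100 * genotypeProb(on, "R/WT"), 1), 2.6)
  expect_equal(round(100 * genotypeProb(off, "R/WT"), 1), 3.7)
  expect_equal(round(100 * genotypeProb(on, "R/R*"), 2), 1.06)
  # maternally induced heterozygotes never arise in this pedigree
  expect_equal(genotypeProb(on, "RSTAR/WT"), 0)
})

test_that("maternal effect reroutes heterozygote flow into homozygotes", {
  # off-case R/+ equals on-case R/+ plus R/R*: the zygotic operator
  # converts part of the resistant-heterozygote flow, creating none
  on <- pedigreeG2(params); off <- pedigreeG2(params, FALSE)
  expect_equal(genotypeProb(off, "R/WT"),
               genotypeProb(on, "R/WT") + genotypeProb(on, "R/R*"))
})

test_that("G2 homozygous-resistant frequency is monotone in y, zero at y = 0", {
  prev <- -1
  for (y in seq(0, 1, by = 0.1)) {
    p <- genotypeProb(pedigreeG2(DriveParams(0.95, y)), "R/R*")
    expect_gte(p, prev)
    prev <- p
  }
  expect_equal(genotypeProb(pedigreeG2(DriveParams(0.95, 0)), "R/R*"), 0)
})

test_that("deterministic backcross recursion reproduces the pedigree", {
  tr <- propagateDrive(founderCohort("GD/WT", "male"),
                       matingScheme("backcross_to_wildtype"), params, 2)
  g2 <- genotypeTrajectory(tr)["G2", ]
  ped <- genotypeProbs(pedigreeG2(params))
  expect_equal(g2[names(ped)], ped)
  expect_equal(sum(g2), 1)
})

test_that("degenerate deterministic trajectories behave", {
  # nothing released: all wild type forever
  tr0 <- propagateDrive(releaseState(0), matingScheme("random_mating"),
                        params, 4)
  expect_true(all(alleleTrajectory(tr0)[, "WT"] == 1))
  # perfect homing, no maternal effect: drive frequency non-decreasing
  tr1 <- propagateDrive(releaseState(0.5, sex = "male"),
                        matingScheme("random_mating"), DriveParams(1, 0), 6)
  gd <- alleleTrajectory(tr1)[, "GD"]
  expect_true(all(diff(gd) >= -1e-12))
  expect_false(any(alleleTrajectory(tr1)[, c("R", "RSTAR")] > 0))
})

test_that("trajectory frequencies are conserved and alleles match genotypes", {
  tr <- propagateDrive(releaseState(0.2), matingScheme("random_mating"),
                       params, 5)
  gm <- genotypeTrajectory(tr); am <- alleleTrajectory(tr)
  expect_true(all(abs(rowSums(gm) - 1) < 1e-12))
  expect_true(all(abs(rowSums(am) - 1) < 1e-12))
  for (i in seq_len(nrow(gm)))
    expect_equal(am[i, ], alleleFrequencies(gm[i, ]))
})

test_that("Wright-Fisher runs are seed-reproducible and conserve frequencies", {
  sch <- matingScheme("random_mating")
  a <- wrightFisherDrive(releaseState(0.2), sch, params, 500, 5, seed = 9)
  b <- wrightFisherDrive(releaseState(0.2), sch, params, 500, 5, seed = 9)
  expect_identical(genotypeTrajectory(a), genotypeTrajectory(b))
  c <- wrightFisherDrive(releaseState(0.2), sch, params, 500, 5, seed = 10)
  expect_false(identical(genotypeTrajectory(a), genotypeTrajectory(c)))
  expect_true(all(abs(rowSums(genotypeTrajectory(a)) - 1) < 1e-12))
  expect_error(wrightFisherDrive(releaseState(0.2), sch, params, 1, 2, 1),
               "popSize")
})

test_that("Wright-Fisher never creates R* when y = 0", {
  tr <- wrightFisherDrive(releaseState(0.3),
                          matingScheme("random_mating"),
                          DriveParams(0.8, 0), 2000, 8, seed = 4)
  expect_true(all(alleleTrajectory(tr)[, "RSTAR"] == 0))
})

test_that("Wright-Fisher tracks the deterministic recursion at large N", {
  det <- alleleTrajectory(propagateDrive(releaseState(0.2),
                                         matingScheme("random_mating"),
                                         params, 5))
  wf <- alleleTrajectory(wrightFisherDrive(releaseState(0.2),
                                           matingScheme("random_mating"),
                                           params, 1e5, 5, seed = 2))
  # binomial bound sqrt(p(1-p)/2N) per resampling step; drift variance
  # accumulates roughly linearly over generations
  gen <- matrix(seq_len(nrow(det)) - 1L, nrow(det), ncol(det))
  bound <- 3 * sqrt(pmax(gen, 1) * det * (1 - det) / (2 * 1e5)) + 1e-9
  expect_true(all(abs(wf - det)[gen > 0] <= bound[gen > 0]))
  expect_equal(wf[1, ], det[1, ])
})
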
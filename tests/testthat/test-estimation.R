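test_that("mean differences cover the trivial arithmetic cases", {
  expect_equal(meanDifference(c(10, 20, 30), c(10, 20, 30)), 0)
  expect_equal(meanDifference(c(10, 20, 30), c(0, 0, 0)), -20)
  expect_equal(meanDifference(c(0, 10), c(5, 5)), 0)
  expect_error(meanDifference(numeric(), c(1, 2)), "empty")
})

test_that("bootstrap intervals behave on symmetric and sterile designs", {
  set.seed(1)
  ctrl <- rnbinom(20, size = 5, mu = 50)
  same <- bootstrapCI(ctrl, ctrl, nBoot = 1000, seed = 10)
  expect_lte(same$ciLow, 0); expect_gte(same$ciHigh, 0)

  sterile <- bootstrapCI(ctrl, rep(0, 20), nBoot = 1000, seed = 11)
  expect_equal(sterile$delta, -mean(ctrl))
  expect_lt(sterile$ciHigh, 0)   # effect size outside the 95% CI: significant

  expect_warning(z <- bootstrapCI(c(5, 5, 5), c(5, 5, 5), nBoot = 100,
                                  seed = 1),
                 "constant")
  expect_equal(z$ciLow, 0); expect_equal(z$ciHigh, 0)
})

test_that("the bootstrap resampling protocol matches an independent oracle", {
  set.seed(2)
  ctrl <- rnbinom(12, size = 4, mu = 40)
  grp <- rnbinom(15, size = 4, mu = 25)
  oracleDeltas <- bootOracleDeltas(ctrl, grp, nBoot = 200, seed = 77)
  ci <- bootstrapCI(ctrl, grp, nBoot = 200, method = "percentile", seed = 77)
  expect_equal(ci$ciLow, unname(quantile(oracleDeltas, 0.025)))
  expect_equal(ci$ciHigh, unname(quantile(oracleDeltas, 0.975)))
  # and the same protocol under the same seed is exactly reproducible
  ci2 <- bootstrapCI(ctrl, grp, nBoot = 200, method = "percentile", seed = 77)
  expect_identical(ci, ci2)
})

test_that("BCa intervals cover a known normal-shift truth at nominal rate", {
  set.seed(3)
  trueDelta <- 4
  hits <- 0L
  nRep <- 1000
  for (r in seq_len(nRep)) {
    c0 <- rnorm(20, 50, 8)
    g0 <- rnorm(20, 50 + trueDelta, 8)
    ci <- bootstrapCI(c0, g0, nBoot = 600, seed = r)
    if (ci$ciLow <= trueDelta && trueDelta <= ci$ciHigh) hits <- hits + 1L
  }
  coverage <- hits / nRep
  expect_gte(coverage, 0.93)
  expect_lte(coverage, 0.97)
})

test_that("permutation p-values agree with exhaustive enumeration", {
  ctrl <- c(1, 2, 3); grp <- c(10, 11, 12)
  exact <- permOracle(ctrl, grp)            # all 20 label splits
  expect_equal(exact, 2 / 20)
  pt <- permutationP(ctrl, grp, nPerm = 4000, seed = 5)
  se <- sqrt(exact * (1 - exact) / 4000)
  expect_lt(abs(pt$p - exact), 2 * se + 1 / 4000 + 1e-9)

  set.seed(8)
  ctrl2 <- rnbinom(6, size = 3, mu = 20); grp2 <- rnbinom(6, size = 3, mu = 14)
  exact2 <- permOracle(ctrl2, grp2)
  pt2 <- permutationP(ctrl2, grp2, nPerm = 6000, seed = 9)
  se2 <- sqrt(exact2 * (1 - exact2) / 6000)
  expect_lt(abs(pt2$p - exact2), 2 * se2 + 1 / 6000 + 1e-9)
})

test_that("identical groups give large p and sterile groups give the bound", {
  set.seed(4)
  ctrl <- rnbinom(20, size = 5, mu = 50)
  same <- permutationP(ctrl, ctrl, nPerm = 500, seed = 6)
  expect_gt(same$p, 0.5)
  sterile <- permutationP(ctrl, rep(0, 20), nPerm = 10000, seed = 7)
  expect_true(sterile$isBound)
  expect_lt(sterile$p, 1e-3)
  expect_gte(sterile$p, 1 / 10001)
  expect_warning(permutationP(c(1, 2), c(3, 4), nPerm = 50, seed = 1),
                 "coarse")
})

test_that("shared-control effect sizes flag only the real defects", {
  fd <- simulateFertility(list(wildtype = list(mean = 50, dispersion = 5),
                               het_A = list(mean = 50, dispersion = 5),
                               null = "sterile"),
                          n = 20, seed = 12)
  es <- effectSizes(fd, nBoot = 1000, nPerm = 2000, seed = 12)
  expect_identical(nrow(es), 2L)
  nullRow <- es[grepl("null", es$comparison), ]
  expect_true(nullRow$significant)
  expect_equal(nullRow$delta,
               -mean(fd$progeny[fd$genotype == "wildtype"]))
  hetRow <- es[grepl("het_A", es$comparison), ]
  expect_false(hetRow$significant)
  expect_error(effectSizes(fd, control = "missing"), "not in data")
})
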
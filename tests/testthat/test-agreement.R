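test_that("paired differences are baseline minus repeat", {
  expect_equal(paired_differences(10.8, 11.7), -0.9)
  expect_equal(paired_differences(c(1, 2), c(0, 4)), c(1, -2))
  expect_equal(paired_differences(c(3, 3, 3), c(3, 3, 3)), c(0, 0, 0))
  expect_error(paired_differences(1:3, 1:4), "equal length")
})

test_that("Bland-Altman limits bracket the mean difference symmetrically", {
  ba <- bland_altman(c(-1, 0, 1))
  expect_equal(ba$mean_diff, 0)
  expect_equal(ba$loa_low, -1.96)
  expect_equal(ba$loa_high, 1.96)
  ba2 <- bland_altman(c(2, 4, 6, 8))
  expect_equal(ba2$mean_diff, 5)
  expect_equal(ba2$sd_diff, sqrt(20 / 3))
  expect_equal(ba2$loa_low, 5 - 1.96 * sqrt(20 / 3))
  expect_equal(ba2$loa_high, 5 + 1.96 * sqrt(20 / 3))
  ba3 <- bland_altman(rep(2.5, 5))
  expect_equal(c(ba3$loa_low, ba3$loa_high), c(2.5, 2.5))
  # midpoint and width invariants on random inputs
  set.seed(30)
  for (i in 1:20) {
    d <- rnorm(sample(3:40, 1), sd = runif(1, 0.1, 10))
    ba <- bland_altman(d)
    expect_equal((ba$loa_low + ba$loa_high) / 2, ba$mean_diff)
    expect_equal(ba$loa_high - ba$loa_low, 2 * 1.96 * ba$sd_diff)
  }
  expect_error(bland_altman(c(1, 2)), "at least 3")
})

test_that("concordance correlation matches hand-computed cases and its properties", {
  expect_equal(concordance_correlation(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(concordance_correlation(c(1, 2, 3), c(3, 2, 1)), -1)
  expect_equal(concordance_correlation(c(1, 2, 3), c(2, 3, 4)), 4 / 7)
  set.seed(31)
  for (i in 1:50) {
    n <- sample(3:30, 1)
    x <- rnorm(n); y <- rnorm(n, mean = runif(1, -2, 2))
    ccc <- concordance_correlation(x, y)
    # symmetry, range, and domination by |Pearson|
    expect_equal(ccc, concordance_correlation(y, x))
    expect_true(ccc >= -1 && ccc <= 1)
    expect_lte(abs(ccc), abs(cor(x, y)) + 1e-12)
  }
  # equality with Pearson iff means and variances agree
  x <- rnorm(50)
  expect_equal(concordance_correlation(x, x), 1)
  expect_error(concordance_correlation(c(1, 1, 1), c(1, 2, 3)), "non-constant")
})

test_that("Sandvik-Olsson statistic tracks which condition is more dispersed", {
  # identical series: defined degenerate case
  d <- c(-2, 0, 2, -4)
  expect_equal(sandvik_olsson(d, d), list(rho = 0, p = 1, n = 4,
                                          method = "degenerate"))
  # first series twice as dispersed: perfect positive rank agreement
  so <- sandvik_olsson(c(-2, 0, 2, -4), c(-1, 0, 1, -2))
  expect_equal(so$rho, 1)
  # flipped roles: perfect negative
  so2 <- sandvik_olsson(c(-1, 0, 1, -2), c(-2, 0, 2, -4))
  expect_equal(so2$rho, -1)
  # exact permutation p at small n detects a strong dispersion contrast
  set.seed(99)
  z8 <- rnorm(8)
  so3 <- sandvik_olsson(2 * z8, z8 / 2)
  expect_equal(so3$method, "exact permutation")
  expect_equal(so3$rho, 1)
  expect_lt(so3$p, 0.01) # only the two sign-perfect orderings reach |rho| = 1
  expect_error(sandvik_olsson(1:4, 1:5), "equal length")
  expect_error(sandvik_olsson(1:3, 1:3), "at least 4")
})

test_that("Levene's test matches the hand-worked ANOVA on absolute deviations", {
  lv0 <- levene_test(c(-1, 0, 1), c(-1, 0, 1))
  expect_equal(lv0$statistic, 0)
  lv <- levene_test(c(-1, 0, 1), c(-2, 0, 2))
  expect_equal(lv$statistic, 0.8)
  expect_equal(lv$df, c(1, 4))
  expect_equal(lv$p, pf(0.8, 1, 4, lower.tail = FALSE))
  # clearly unequal spreads are detected
  set.seed(32)
  lv2 <- levene_test(rnorm(100, sd = 1), rnorm(100, sd = 3))
  expect_lt(lv2$p, 0.001)
  # agrees with the car reference implementation when centred at the mean
  g1 <- rnorm(25); g2 <- rnorm(30, sd = 2)
  ours <- levene_test(g1, g2)
  ref <- car::leveneTest(c(g1, g2), factor(rep(1:2, c(25, 30))), center = mean)
  expect_equal(ours$statistic, ref[1, "F value"], tolerance = 1e-12)
  expect_equal(ours$p, ref[1, "Pr(>F)"], tolerance = 1e-12)
  expect_error(levene_test(c(1, 1, 1), c(2, 2, 2)), "degenerate")
})

test_that("outer-quartile subgrouping is deterministic, stable and shift-invariant", {
  lab8 <- breath_hold_subgroups(1:8)
  expect_equal(as.character(lab8),
               rep(c("inferior", "superior", "inferior"), c(2, 4, 2)))
  lab4 <- breath_hold_subgroups(c(1, 2, 3, 4), min_n = 4)
  expect_equal(as.character(lab4), c("inferior", "superior", "superior", "inferior"))
  set.seed(33)
  dv <- rnorm(45)
  lab <- breath_hold_subgroups(dv)
  expect_equal(unname(table(lab)["inferior"]), 22L, ignore_attr = TRUE)
  expect_equal(unname(table(lab)["superior"]), 23L, ignore_attr = TRUE)
  # adding a constant does not change the labels
  expect_identical(lab, breath_hold_subgroups(dv + 17.3))
  # ties are broken by input order
  expect_identical(breath_hold_subgroups(rep(1, 8)),
                   factor(rep(c("inferior", "superior", "inferior"), c(2, 4, 2)),
                          levels = c("inferior", "superior")))
  expect_error(breath_hold_subgroups(1:5), "at least 8")
})
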
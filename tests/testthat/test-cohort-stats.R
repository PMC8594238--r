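test_that("Lilliefors normality test is calibrated and detects gross departure", {
  set.seed(101)
  x <- rnorm(10000, 0.3, 0.05)
  expect_gt(ks_normality(x)$p_value, 0.05)
  bimodal <- rep(c(0.2, 0.8), each = 100) + rnorm(200, 0, 1e-6)
  expect_lt(ks_normality(bimodal)$p_value, 0.01)
  expect_error(ks_normality(rep(0.3, 50)), "zero-variance")
  expect_error(ks_normality(c(1, 2, 3)), "n >= 5")
})

test_that("Levene test recognises equal and unequal spread", {
  g <- c(1, 2, 3, 4)
  res <- levene_test(list(a = g, b = g))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  set.seed(7)
  het <- list(a = rnorm(100, 0, 5), b = rnorm(100, 0, 1))
  expect_lt(levene_test(het)$p_value, 0.01)
  expect_error(levene_test(list(a = g)), "2 groups")
})

test_that("Levene p-values are uniform under the homoscedastic null", {
  set.seed(21)
  pooled <- rnorm(60, 0.3, 0.05)
  ps <- replicate(200, {
    idx <- sample(60, 30)
    levene_test(list(a = pooled[idx], b = pooled[-idx]))$p_value
  })
  expect_lt(abs(mean(ps) - 0.5), 0.08)
})

test_that("pooled t-test degenerates and symmetrizes correctly", {
  a <- c(0.30, 0.32, 0.29, 0.35)
  res <- t_test_independent(a, a)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  expect_equal(res$df, 6)
  set.seed(3)
  b <- rnorm(10, 0.4, 0.05)
  r1 <- t_test_independent(a, b); r2 <- t_test_independent(b, a)
  expect_equal(r1$p_value, r2$p_value)
  expect_equal(r1$statistic, -r2$statistic)
  # zero pooled variance
  expect_equal(t_test_independent(c(1, 1), c(1, 1))$p_value, 1)
  expect_error(t_test_independent(c(1, 1), c(2, 2)), "infinite")
  expect_error(t_test_independent(1, c(1, 2)), "n >= 2")
})

test_that("the t-test nearly always separates the published effect sizes", {
  # group means 0.34 vs 0.26, SDs 0.07 / 0.03, n = 21 per group
  rej <- vapply(1:1000, function(k) {
    set.seed(k)
    a <- rnorm(21, 0.34, 0.07); b <- rnorm(21, 0.26, 0.03)
    t_test_independent(a, b)$p_value < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.99)
})

test_that("one-way ANOVA matches its algebraic identities", {
  # identical groups: no between-group variation
  g <- c(0.3, 0.31, 0.29)
  res0 <- one_way_anova(list(a = g, b = g, c = g))
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p_value, 1)
  # two groups: F = t^2, same p
  set.seed(5)
  a <- rnorm(15, 0.3, 0.05); b <- rnorm(12, 0.33, 0.05)
  fa <- one_way_anova(list(a = a, b = b))
  tt <- t_test_independent(a, b)
  expect_equal(fa$statistic, tt$statistic^2, tolerance = 1e-12)
  expect_equal(fa$p_value, tt$p_value, tolerance = 1e-12)
  expect_error(one_way_anova(list(a = a, b = 1)), "n >= 2")
})

test_that("summary-statistic ANOVA agrees with raw-data ANOVA", {
  for (s in 1:5) {
    set.seed(s)
    gs <- lapply(c(21, 19, 18), function(n) rnorm(n, runif(1, .2, .4), .05))
    raw <- one_way_anova(gs, pairwise = FALSE)
    summ <- anova_from_summary(vapply(gs, mean, 0), vapply(gs, sd, 0),
                               lengths(gs))
    expect_equal(summ$statistic, raw$statistic, tolerance = 1e-10)
    expect_equal(summ$p_value, raw$p_value, tolerance = 1e-10)
  }
  expect_equal(anova_from_summary(c(1, 1), c(2, 2), c(5, 5))$statistic, 0)
  expect_error(anova_from_summary(c(1, 2), c(1), c(5, 5)), "equal length")
})

test_that("published demographics show no group differences", {
  age <- anova_from_summary(c(56.67, 57.05, 54.72, 54.05),
                            c(10.96, 13.02, 13.20, 14.17),
                            c(21, 19, 18, 21))
  expect_gte(age$p_value, 0.05)
  sex <- matrix(c(12, 9, 9, 10, 10, 8, 13, 8), nrow = 2)
  expect_gte(chi_square(sex)$p_value, 0.05)
})

test_that("chi-square matches the definition and handles degenerate tables", {
  tab <- matrix(c(20, 10, 40, 20), nrow = 2)  # identical column proportions
  res <- chi_square(tab)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  # brute force from sum((O - E)^2 / E) on a 2x2 table
  t2 <- matrix(c(12, 9, 13, 8), nrow = 2)
  E <- outer(rowSums(t2), colSums(t2)) / sum(t2)
  expect_equal(chi_square(t2)$statistic, sum((t2 - E)^2 / E),
               tolerance = 1e-12)
  expect_equal(chi_square(t2)$df, 1)
  expect_error(chi_square(matrix(c(0, 0, 5, 5), 2)), "marginals")
  expect_error(chi_square(matrix(c(-1, 2, 3, 4), 2)), "nonnegative")
})

test_that("the exact noncentral-t sample-size solver is tight and monotone", {
  n <- sample_size_two_sample_t(delta = 0.1, sigma = 0.05)
  expect_identical(n, 6L)
  expect_gte(two_sample_t_power(n, 0.1, 0.05), 0.8)
  expect_lt(two_sample_t_power(n - 1, 0.1, 0.05), 0.8)
  # doubling delta never increases the requirement
  deltas <- c(0.05, 0.1, 0.2, 0.4)
  ns <- vapply(deltas, sample_size_two_sample_t, 0L, sigma = 0.05)
  expect_true(all(diff(ns) <= 0))
  expect_error(sample_size_two_sample_t(0, 0.05), "delta")
  # independent cross-check against stats::power.t.test
  for (par in list(c(0.1, 0.05), c(0.5, 0.4), c(1, 1))) {
    expect_identical(
      sample_size_two_sample_t(par[1], par[2]),
      as.integer(ceiling(power.t.test(delta = par[1], sd = par[2],
                                      power = 0.8)$n)))
  }
})
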
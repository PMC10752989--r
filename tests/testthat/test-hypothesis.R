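test_that("KS normality gate rejects non-normal data and stays conservative under normality", {
  expect_error(ks_normality(rep(1, 10)), "constant")
  expect_error(ks_normality(c(1, 2)), "at least 5")
  set.seed(51)
  # parameters estimated from the sample make the test conservative:
  # under normality the rejection rate stays below the nominal 5%
  rej_norm <- mean(replicate(200, ks_normality(rnorm(2000))$significant))
  expect_lt(rej_norm, 0.05)
  # consistency: clearly skewed data is flagged essentially always
  rej_exp <- mean(replicate(100, ks_normality(rexp(2000))$significant))
  expect_gt(rej_exp, 0.99)
})

test_that("gated location test picks the t-test for Gaussian data and Wilcoxon otherwise", {
  set.seed(61)
  a <- rnorm(40, 10, 1)
  b <- rnorm(40, 10, 1)
  expect_match(paired_location_test(a, b)$test_name, "t-test")
  a_skew <- rexp(40)
  expect_match(paired_location_test(a_skew, b)$test_name, "Wilcoxon")
  expect_error(paired_location_test(1:10, 1:9), "equal length")
  r <- paired_location_test(a, a)
  expect_equal(r$p_value, 1)
  expect_false(r$significant)
})

test_that("exact Wilcoxon p equals full sign-flip enumeration", {
  # fixed example: all-positive differences 1..8 against zero
  a <- c(1, 2, 3, 4, 5, 6, 7, 8)
  r <- paired_location_test(a + 100, rep(100, 8), alpha_normality = 1)
  expect_match(r$test_name, "exact")
  expect_equal(r$p_value, oracle_wilcoxon_p(a), tolerance = 1e-12)
  expect_equal(r$p_value, 2 / 2^8, tolerance = 1e-12)
  # property over random paired data for every n up to 12; differences are
  # passed exactly (a = d, b = 0) so tied magnitudes stay tied
  set.seed(71)
  for (i in 1:60) {
    n <- sample(5:12, 1)
    d <- round(rnorm(n, sd = 3), 1)
    d[d == 0] <- 0.5
    r <- paired_location_test(d, rep(0, n), alpha_normality = 1)
    expect_equal(r$p_value, oracle_wilcoxon_p(d), tolerance = 1e-12,
                 label = paste("n =", n))
  }
})

test_that("gated paired test holds its nominal level under Gaussian and Laplace nulls", {
  set.seed(81)
  rej <- mean(replicate(1000, {
    a <- rnorm(30); b <- rnorm(30)
    paired_location_test(a, b, alpha = 0.01)$significant
  }))
  expect_gte(rej, 0.002)
  expect_lte(rej, 0.025)
  rlaplace <- function(n) rexp(n) - rexp(n)
  rej_l <- mean(replicate(500, {
    a <- rlaplace(30); b <- rlaplace(30)
    paired_location_test(a, b, alpha = 0.01)$significant
  }))
  expect_lte(rej_l, 0.03)
})

test_that("variance F-test matches the F CDF closed form and detects spread differences", {
  a <- c(1, 2, 3, 4, 5)
  r <- variance_f_test(a, a)
  expect_equal(r$statistic, 1)
  expect_equal(r$p_value, 1)
  expect_error(variance_f_test(rep(1, 5), a), "constant")
  set.seed(91)
  x <- rnorm(20, sd = 2)
  y <- rnorm(15, sd = 1)
  r <- variance_f_test(x, y)
  f <- var(x) / var(y)
  # independent route: F CDF through the regularized incomplete beta
  p_beta <- pbeta(19 * f / (19 * f + 14), 19 / 2, 14 / 2)
  expect_equal(r$p_value, min(1, 2 * min(p_beta, 1 - p_beta)), tolerance = 1e-10)
  # power: variance ratio 4 at n = 50 vs 50 is detected nearly always
  det <- mean(replicate(200, {
    variance_f_test(rnorm(50, sd = 2), rnorm(50, sd = 1), alpha = 0.01)$significant
  }))
  expect_gt(det, 0.95)
})

test_that("Fisher z-test matches its closed form and is antisymmetric", {
  r0 <- fisher_z_test(0.5, 50, 0.5, 50)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)
  r <- fisher_z_test(0.9, 103, 0.3, 103)
  z_hand <- (atanh(0.9) - atanh(0.3)) / sqrt(2 / 100)
  expect_equal(r$statistic, z_hand, tolerance = 1e-10)
  expect_equal(r$p_value, 2 * pnorm(-abs(z_hand)), tolerance = 1e-10)
  r_swap <- fisher_z_test(0.3, 103, 0.9, 103)
  expect_equal(r_swap$statistic, -r$statistic, tolerance = 1e-12)
  expect_equal(r_swap$p_value, r$p_value, tolerance = 1e-12)
  expect_error(fisher_z_test(1, 50, 0.5, 50), "< 1")
})

test_that("CI-overlap rule reproduces the published reliability comparisons", {
  # two automated pipelines on a 3T test-retest panel: clearly separated
  expect_true(ci_overlap_significant(0.985, c(0.973, 0.992),
                                     0.893, c(0.813, 0.939)))
  # 7T panel with a small sample: intervals engulf the other estimate
  expect_false(ci_overlap_significant(0.990, c(0.944, 0.998),
                                      0.976, c(0.869, 0.996)))
  expect_false(ci_overlap_significant(0.9, c(0.8, 0.95), 0.9, c(0.8, 0.95)))
  expect_error(ci_overlap_significant(0.9, c(0.95, 0.8), 0.9, c(0.8, 0.95)),
               "malformed")
  expect_error(ci_overlap_significant(0.99, c(0.8, 0.95), 0.9, c(0.8, 0.95)),
               "outside its own")
  # asymmetric variant triggers as soon as one estimate is outside
  expect_true(ci_overlap_significant(0.96, c(0.95, 0.97), 0.90, c(0.85, 0.965),
                                     rule = "asymmetric"))
  expect_false(ci_overlap_significant(0.96, c(0.95, 0.97), 0.90, c(0.85, 0.965)))
})
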
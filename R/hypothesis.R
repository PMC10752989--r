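#' @keywords internal
test_result <- function(test_name, statistic, p_value, alpha,
                        extra = list()) {
  stopifnot(p_value >= 0, p_value <= 1)
  structure(c(list(test_name = test_name,
                   statistic = unname(statistic),
                   p_value = unname(p_value),
                   alpha = alpha,
                   significant = p_value < alpha),
              extra),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.6g, p = %.4g (%ssignificant at alpha = %g)\n",
              x$test_name, x$statistic, x$p_value,
              if (x$significant) "" else "not ", x$alpha))
  invisible(x)
}

#' Kolmogorov-Smirnov normality gate
#'
#' One-sample KS test of the values against a normal distribution with mean
#' and SD estimated from the same sample, with the p-value taken from the
#' asymptotic KS distribution. A significant result (p < alpha) rejects
#' normality. Estimating the parameters from the data makes this test
#' conservative (the true rejection rate under normality is below nominal);
#' that behaviour is kept as is rather than corrected, since it is the
#' gate's stated form.
#'
#' @param values numeric vector, n >= 5, non-constant.
#' @param alpha gate level (default 0.05).
#' @return a `test_result`; `significant = TRUE` means non-Gaussian.
#' @export
ks_normality <- function(values, alpha = 0.05) {
  if (length(values) < 5L) stop("at least 5 values are required")
  s <- stats::sd(values)
  if (!is.finite(s) || s == 0) stop("normality test undefined for constant input")
  ks <- suppressWarnings(
    stats::ks.test(values, "pnorm", mean = mean(values), sd = s)
  )
  test_result("Kolmogorov-Smirnov normality", ks$statistic, ks$p.value, alpha,
              extra = list(n = length(values)))
}

# exact two-sided signed-rank p-value by convolution over sign assignments:
# P(W <= v) and P(W >= v) under the null that each rank enters the positive
# sum independently with probability 1/2. Midranks from ties are handled by
# doubling (all rank sums become integers in half-units).
wilcoxon_exact_p <- function(ranks, v) {
  r2 <- round(2 * ranks)
  total <- sum(r2)
  # f[s + 1] = number of sign assignments with doubled positive-rank sum s
  f <- rep(0, total + 1L)
  f[1L] <- 1
  for (r in r2) {
    shifted <- c(rep(0, r), f[seq_len(length(f) - r)])
    f <- f + shifted
  }
  probs <- f / 2^length(r2)
  v2 <- round(2 * v)
  p_le <- sum(probs[seq_len(v2 + 1L)])
  p_ge <- sum(probs[(v2 + 1L):(total + 1L)])
  min(1, 2 * min(p_le, p_ge))
}

#' Gated paired location test
#'
#' Tests whether two paired samples differ in location, choosing the test
#' with a normality gate: [ks_normality()] is run on each sample at
#' `alpha_normality`, and if either rejects, a Wilcoxon matched-pairs
#' signed-rank test is used; otherwise a paired t-test.
#'
#' The Wilcoxon branch drops zero differences (Wilcoxon's convention),
#' ranks the absolute differences with midranks, and uses the exact null
#' distribution (full sign-flip convolution) when the number of non-zero
#' differences is at most 25, switching to the normal approximation with
#' continuity and tie correction above. Two-sided p-values double the
#' smaller tail, capped at 1. If all differences are zero the test returns
#' statistic 0 and p = 1 (no evidence of a difference).
#'
#' @param a,b paired numeric vectors of equal length >= 5.
#' @param alpha significance level for the location test (default 0.01).
#' @param alpha_normality level of the normality gate (default 0.05).
#' @param exact_max largest sample size for the exact Wilcoxon null.
#' @return a `test_result` whose `test_name` records the chosen test.
#' @export
paired_location_test <- function(a, b, alpha = 0.01, alpha_normality = 0.05,
                                 exact_max = 25L) {
  if (length(a) != length(b)) stop("paired samples must have equal length")
  if (length(a) < 5L) stop("at least 5 pairs are required")
  d <- a - b
  if (all(d == 0)) {
    return(test_result("paired location (degenerate: all differences zero)",
                       0, 1, alpha))
  }
  gaussian <- !ks_normality(a, alpha_normality)$significant &&
    !ks_normality(b, alpha_normality)$significant
  if (gaussian) {
    tt <- stats::t.test(a, b, paired = TRUE)
    return(test_result("paired t-test", tt$statistic, tt$p.value, alpha,
                       extra = list(n = length(a))))
  }
  d <- d[d != 0]
  n <- length(d)
  rk <- rank(abs(d))
  v <- sum(rk[d > 0])
  if (n <= exact_max) {
    p <- wilcoxon_exact_p(rk, v)
    name <- "Wilcoxon signed-rank (exact)"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(rk)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (v - mu - sign(v - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    name <- "Wilcoxon signed-rank (normal approximation)"
  }
  test_result(name, v, p, alpha, extra = list(n = n))
}

#' F-test comparing two variances
#'
#' `F = s_a^2 / s_b^2` on (n_a - 1, n_b - 1) degrees of freedom, two-sided
#' p-value by doubling the smaller tail of the F distribution. Used to
#' compare the precision (spread of percent errors) of two measurement
#' methods.
#'
#' @param a,b numeric samples, each of length >= 3 and non-constant.
#' @param alpha significance level (default 0.01).
#' @return a `test_result` with `df1`, `df2` attached.
#' @export
variance_f_test <- function(a, b, alpha = 0.01) {
  if (length(a) < 3L || length(b) < 3L) stop("both samples need at least 3 values")
  va <- stats::var(a)
  vb <- stats::var(b)
  if (va == 0 || vb == 0) stop("variance test undefined for constant input")
  f <- va / vb
  df1 <- length(a) - 1L
  df2 <- length(b) - 1L
  p <- min(1, 2 * min(stats::pf(f, df1, df2), stats::pf(f, df1, df2, lower.tail = FALSE)))
  test_result("F-test of variances", f, p, alpha,
              extra = list(df1 = df1, df2 = df2))
}

#' Fisher z-test comparing two correlation coefficients
#'
#' Treats the two correlations as arising from independent samples:
#' `z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1 - 3) + 1/(n2 - 3))`,
#' two-sided p from the standard normal. When both correlations involve a
#' shared reference variable (e.g. two automated methods each correlated
#' with the same manual volumes) the independence assumption is only
#' approximate; the test is nevertheless computed in this standard form.
#'
#' @param r1,r2 correlation coefficients with |r| < 1.
#' @param n1,n2 sample sizes (>= 4).
#' @param alpha significance level (default 0.01).
#' @return a `test_result` with statistic z.
#' @export
fisher_z_test <- function(r1, n1, r2, n2, alpha = 0.01) {
  if (abs(r1) >= 1 || abs(r2) >= 1) stop("|r| must be < 1 (Fisher transform diverges)")
  if (n1 < 4L || n2 < 4L) stop("both sample sizes must be >= 4")
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  test_result("Fisher z-test of correlations", z, p, alpha)
}

#' Confidence-interval overlap significance rule
#'
#' Two interval estimates are declared significantly different when
#' neither point estimate falls inside the other's confidence interval.
#' The default is this symmetric (conservative) reading; `rule =
#' "asymmetric"` declares significance as soon as one estimate falls
#' outside the other's interval.
#'
#' @param est_a,est_b point estimates.
#' @param ci_a,ci_b length-2 numeric intervals `c(low, high)` containing
#'   their own estimates.
#' @param rule `"symmetric"` (default) or `"asymmetric"`.
#' @return logical: `TRUE` if significantly different.
#' @export
ci_overlap_significant <- function(est_a, ci_a, est_b, ci_b,
                                   rule = c("symmetric", "asymmetric")) {
  rule <- match.arg(rule)
  check_ci <- function(est, ci, label) {
    if (length(ci) != 2L || anyNA(ci)) stop("interval ", label, " must be c(low, high)")
    if (ci[1L] > ci[2L]) stop("malformed interval ", label, ": low > high")
    if (est < ci[1L] || est > ci[2L]) {
      stop("estimate ", label, " lies outside its own confidence interval")
    }
  }
  check_ci(est_a, ci_a, "a")
  check_ci(est_b, ci_b, "b")
  a_outside_b <- est_a < ci_b[1L] || est_a > ci_b[2L]
  b_outside_a <- est_b < ci_a[1L] || est_b > ci_a[2L]
  if (rule == "symmetric") a_outside_b && b_outside_a else a_outside_b || b_outside_a
}
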
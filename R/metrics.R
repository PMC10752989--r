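#' Volume percentage error
#'
#' Signed percent deviation of a predicted volume from the ground truth:
#' `100 * (v_pred - v_gt) / v_gt`. Underestimation is negative. The mean
#' over subjects measures systematic bias; the SD measures precision.
#'
#' @param v_pred predicted volume(s), vectorized.
#' @param v_gt ground-truth volume(s), must be positive.
#' @return signed percent error(s).
#' @export
vpe <- function(v_pred, v_gt) {
  if (any(!is.finite(v_gt)) || any(v_gt <= 0)) {
    stop("ground-truth volumes must be positive")
  }
  100 * (v_pred - v_gt) / v_gt
}

#' Volume percentage difference
#'
#' Symmetric percent difference between test and retest measurements of the
#' same subject: `100 * 2 * |v_test - v_retest| / (v_test + v_retest)`.
#' Zero iff the two volumes agree; invariant to a common rescaling of both;
#' bounded above by 200. Lower values indicate better test-retest
#' reliability.
#'
#' @param v_test,v_retest positive volumes, vectorized.
#' @return non-negative percent difference(s).
#' @export
vpd <- function(v_test, v_retest) {
  if (any(v_test <= 0) || any(v_retest <= 0)) {
    stop("volumes must be positive")
  }
  100 * 2 * abs(v_test - v_retest) / (v_test + v_retest)
}

#' Summary statistics of a percent-error distribution
#'
#' Median, mean, 25th/75th percentiles (linear interpolation between order
#' statistics) and sample standard deviation (n - 1 denominator), the
#' columns of the standard accuracy summary table.
#'
#' @param values numeric vector (>= 2 values for a defined SD).
#' @return a one-row data frame with columns `median`, `mean`, `p25`,
#'   `p75`, `sd`, `n`.
#' @export
vpe_summary <- function(values) {
  if (length(values) == 0L || anyNA(values)) stop("values must be non-empty and complete")
  if (length(values) < 2L) stop("at least 2 values are required for a sample SD")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  data.frame(median = q[2L], mean = mean(values), p25 = q[1L], p75 = q[3L],
             sd = stats::sd(values), n = length(values))
}

#' Pearson correlation with interpretation band
#'
#' Sample Pearson correlation between predicted and reference volumes,
#' labelled with the conventional interpretation bands: r > 0.9 very
#' strong, 0.7 < r <= 0.9 strong, 0.4 < r <= 0.7 moderate, r <= 0.4 weak
#' or negligible (cut points are open at the top, so a boundary value
#' falls into the lower band).
#'
#' @param x,y numeric vectors of equal length >= 3, neither constant.
#' @return list with elements `r` and `band`.
#' @export
pearson_cc <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("at least 3 pairs are required")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for constant input")
  }
  r <- stats::cor(x, y, method = "pearson")
  list(r = r, band = cc_band(r))
}

#' @rdname pearson_cc
#' @param r a correlation coefficient.
#' @export
cc_band <- function(r) {
  stopifnot(is.finite(r), abs(r) <= 1)
  if (r > 0.9) "very strong"
  else if (r > 0.7) "strong"
  else if (r > 0.4) "moderate"
  else "weak or negligible"
}

#' Intraclass correlation: two-way mixed, consistency, single rater
#'
#' ICC(C,1) from the two-way ANOVA without interaction on an n x k
#' subjects-by-sessions matrix: with MS_R the between-subjects mean square
#' and MS_E the residual mean square after removing the session effect,
#' `ICC = (MS_R - MS_E) / (MS_R + (k - 1) * MS_E)`. Because the session
#' effect is removed, a constant offset added to one session leaves the
#' estimate unchanged (consistency, not absolute agreement).
#'
#' The two-sided confidence interval is the F-based one: `F = MS_R / MS_E`
#' on (n - 1, (n - 1)(k - 1)) degrees of freedom, each bound mapped back
#' through `(F/F_crit - 1) / (F/F_crit + k - 1)`.
#'
#' Reliability bands: estimate < 0.75 poor, 0.75 to 0.95 good, > 0.95
#' excellent (boundaries fall in the lower band).
#'
#' @param m numeric matrix, rows = subjects (n >= 3), columns = sessions
#'   (k >= 2), no missing cells.
#' @param alpha two-sided CI level is `1 - alpha` (default 95%).
#' @return an object of class `icc_result`: list with `estimate`,
#'   `ci_low`, `ci_high`, `n_subjects`, `k_sessions`, `model_label`,
#'   `band`, `alpha`.
#' @export
icc_consistency <- function(m, alpha = 0.05) {
  m <- as.matrix(m)
  if (anyNA(m)) stop("missing cells are not allowed; analyses use complete pairs only")
  n <- nrow(m)
  k <- ncol(m)
  if (n < 3L) stop("at least 3 subjects are required")
  if (k < 2L) stop("at least 2 sessions are required")
  grand <- mean(m)
  if (sum((m - grand)^2) == 0) stop("zero total variance; ICC undefined")
  row_means <- rowMeans(m)
  col_means <- colMeans(m)
  ss_rows <- k * sum((row_means - grand)^2)
  ss_cols <- n * sum((col_means - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  ms_r <- ss_rows / (n - 1)
  ms_e <- ss_err / ((n - 1) * (k - 1))
  est <- (ms_r - ms_e) / (ms_r + (k - 1) * ms_e)
  if (ms_e == 0) {
    ci <- c(est, est)  # degenerate: no residual variance
  } else {
    f_obs <- ms_r / ms_e
    df1 <- n - 1
    df2 <- (n - 1) * (k - 1)
    fl <- f_obs / stats::qf(1 - alpha / 2, df1, df2)
    fu <- f_obs * stats::qf(1 - alpha / 2, df2, df1)
    ci <- c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1))
  }
  structure(list(estimate = est, ci_low = ci[1L], ci_high = ci[2L],
                 n_subjects = n, k_sessions = k,
                 model_label = "two-way mixed, consistency, single rater",
                 band = icc_band(est), alpha = alpha),
            class = "icc_result")
}

#' @rdname icc_consistency
#' @param estimate an ICC point estimate.
#' @export
icc_band <- function(estimate) {
  if (estimate > 0.95) "excellent"
  else if (estimate >= 0.75) "good"
  else "poor"
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC (%s): %.4f, %d%% CI [%.4f, %.4f] (%s reliability)\n",
              x$model_label, x$estimate, round(100 * (1 - x$alpha)),
              x$ci_low, x$ci_high, x$band))
  cat(sprintf("  n = %d subjects, k = %d sessions\n", x$n_subjects, x$k_sessions))
  invisible(x)
}
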
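# Independent oracles used across tests. Each recomputes a quantity by a
# different route than the package implementation (explicit summation or
# full enumeration), so agreement is evidence rather than tautology.

# Pearson correlation by direct summation of raw moments.
oracle_pearson <- function(x, y) {
  n <- length(x)
  sx <- 0; sy <- 0; sxx <- 0; syy <- 0; sxy <- 0
  for (i in seq_len(n)) {
    sx <- sx + x[i]; sy <- sy + y[i]
    sxx <- sxx + x[i]^2; syy <- syy + y[i]^2; sxy <- sxy + x[i] * y[i]
  }
  num <- sxy - sx * sy / n
  den <- sqrt((sxx - sx^2 / n) * (syy - sy^2 / n))
  num / den
}

# Consistency ICC by an explicit two-way ANOVA decomposition with loops.
oracle_icc <- function(m) {
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  ss_rows <- 0
  for (i in seq_len(n)) ss_rows <- ss_rows + k * (mean(m[i, ]) - grand)^2
  ss_cols <- 0
  for (j in seq_len(k)) ss_cols <- ss_cols + n * (mean(m[, j]) - grand)^2
  ss_err <- 0
  for (i in seq_len(n)) for (j in seq_len(k)) {
    ss_err <- ss_err + (m[i, j] - mean(m[i, ]) - mean(m[, j]) + grand)^2
  }
  ms_r <- ss_rows / (n - 1)
  ms_e <- ss_err / ((n - 1) * (k - 1))
  (ms_r - ms_e) / (ms_r + (k - 1) * ms_e)
}

# Exact two-sided Wilcoxon signed-rank p-value by brute-force enumeration
# of all 2^n sign assignments (feasible for n <= ~14).
oracle_wilcoxon_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  rk <- rank(abs(d))
  v <- sum(rk[d > 0])
  total <- 2^n
  sums <- numeric(total)
  for (a in 0:(total - 1)) {
    bits <- as.integer(intToBits(a))[1:n]
    sums[a + 1] <- sum(rk[bits == 1L])
  }
  p_le <- mean(sums <= v)
  p_ge <- mean(sums >= v)
  min(1, 2 * min(p_le, p_ge))
}

# single-observation table used in the closed-form log-posterior checks
one_obs_table <- function(volume = 2.5, t = 3) {
  volume_table(data.frame(subject_id = "s1", method = "m", roi = "r",
                          session = "v1", time_months = t, volume = volume),
               require_positive = FALSE)
}

# small helper to extract one summary row from a blme fit
blme_summary_value <- function(fit, param, col = "mean", scale = "fit") {
  s <- if (scale == "raw") fit$summaries_raw else fit$summaries
  s[s$parameter == param, col]
}
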
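test_that("log posterior matches a hand-computed five-term case", {
  tab <- one_obs_table(volume = 2.5, t = 3)
  spec <- blme_spec(prior_loc_sd = 10, prior_scale = 5)
  params <- list(alpha0 = 1, beta0 = -0.5, tau = 2, sigma = 1.5, rho = 0.7,
                 alpha = 1.2, beta = -0.4)
  # hand-built from the closed-form normal and half-Cauchy log densities
  mu <- 1.2 + (-0.4) * 3
  expected <- dnorm(2.5, mu, 1.5, log = TRUE) +
    dnorm(1.2, 1, 2, log = TRUE) +
    dnorm(-0.4, -0.5, 0.7, log = TRUE) +
    dnorm(1, 0, 10, log = TRUE) +
    dnorm(-0.5, 0, 10, log = TRUE) +
    (log(2) + dcauchy(1.5, 0, 5, log = TRUE)) +
    (log(2) + dcauchy(2, 0, 5, log = TRUE)) +
    (log(2) + dcauchy(0.7, 0, 5, log = TRUE))
  expect_equal(blme_log_posterior(params, tab, spec), expected,
               tolerance = 1e-12)
})

test_that("log posterior is additive in observations and rejects zero scales", {
  tab1 <- one_obs_table()
  df2 <- rbind(as.data.frame(tab1), as.data.frame(tab1))
  df2$session <- c("v1", "v2")
  tab2 <- volume_table(df2, require_positive = FALSE)
  spec <- blme_spec()
  params <- list(alpha0 = 1, beta0 = -0.5, tau = 2, sigma = 1.5, rho = 0.7,
                 alpha = 1.2, beta = -0.4)
  lik_term <- dnorm(2.5, 1.2 - 0.4 * 3, 1.5, log = TRUE)
  expect_equal(blme_log_posterior(params, tab2, spec),
               blme_log_posterior(params, tab1, spec) + lik_term,
               tolerance = 1e-12)
  params$sigma <- 0
  expect_identical(blme_log_posterior(params, tab1, spec), -Inf)
  params$sigma <- 1e-12
  expect_lt(blme_log_posterior(params, tab1, spec), -1e6)
})

test_that("the fit recovers generative parameters and is deterministic", {
  # point recovery is judged on the mean over cohorts: at 40 subjects the
  # cohort-to-cohort spread of the realized variance components is of the
  # same order as the recovery tolerance itself
  tau_hat <- sigma_hat <- r_hat <- numeric(3)
  covered <- 0L
  for (k in 1:3) {
    cfg <- sim_config(40, c(0, 3, 6, 9, 12), alpha0 = 0, beta0 = -0.02,
                      tau = 1.0, rho = 0.02, sigma = 0.2, seed = 42 + k)
    fit <- fit_blme(simulate_longitudinal(cfg), blme_spec(seed = 7 + k))
    expect_true(all(fit$rhat <= 1.01, na.rm = TRUE))
    tau_hat[k] <- blme_summary_value(fit, "tau", scale = "raw")
    sigma_hat[k] <- blme_summary_value(fit, "sigma", scale = "raw")
    r_hat[k] <- variance_ratio(fit)$mean
    if (blme_summary_value(fit, "tau", "ci_low", "raw") <= 1 &&
        1 <= blme_summary_value(fit, "tau", "ci_high", "raw")) {
      covered <- covered + 1L
    }
    # positivity of every retained scale draw, and r defined per draw
    expect_true(all(fit$draws$tau > 0 & fit$draws$sigma > 0 &
                      fit$draws$rho > 0))
    expect_equal(fit$draws$r, fit$draws$tau / fit$draws$sigma)
  }
  expect_equal(mean(tau_hat), 1.0, tolerance = 0.2)
  expect_equal(mean(sigma_hat), 0.2, tolerance = 0.2)
  expect_gt(mean(r_hat), 3.5)
  expect_lt(mean(r_hat), 6.5)
  expect_gte(covered, 2L)
  # identical spec (including seed) reproduces the draws exactly
  cfg <- sim_config(40, c(0, 3, 6, 9, 12), alpha0 = 0, beta0 = -0.02,
                    tau = 1.0, rho = 0.02, sigma = 0.2, seed = 42)
  tab <- simulate_longitudinal(cfg)
  fit1 <- fit_blme(tab, blme_spec(seed = 7, n_warmup = 300, n_draws = 400,
                                  rhat_max = Inf))
  fit2 <- fit_blme(tab, blme_spec(seed = 7, n_warmup = 300, n_draws = 400,
                                  rhat_max = Inf))
  expect_identical(fit1$draws, fit2$draws)
})

test_that("posterior agrees with an independent JAGS fit of the same model", {
  skip_if_not_installed("rjags")
  cfg <- sim_config(30, c(0, 4, 8, 12), alpha0 = 0, beta0 = -0.02,
                    tau = 1.0, rho = 0.03, sigma = 0.25, seed = 13)
  tab <- simulate_longitudinal(cfg)
  fit <- fit_blme(tab, blme_spec(seed = 2))
  df <- as.data.frame(tab)
  y <- df$volume
  yst <- (y - mean(y)) / sd(y)
  subjects <- sort(unique(df$subject_id))
  data <- list(y = yst, t = df$time_months,
               subj = match(df$subject_id, subjects),
               N = nrow(df), n = length(subjects))
  model_str <- "model {
    for (k in 1:N) { y[k] ~ dnorm(alpha[subj[k]] + beta[subj[k]] * t[k], 1/sigma^2) }
    for (i in 1:n) { alpha[i] ~ dnorm(alpha0, 1/tau^2); beta[i] ~ dnorm(beta0, 1/rho^2) }
    alpha0 ~ dnorm(0, 0.01); beta0 ~ dnorm(0, 0.01)
    sigma ~ dt(0, 1/25, 1) T(0,); tau ~ dt(0, 1/25, 1) T(0,); rho ~ dt(0, 1/25, 1) T(0,)
  }"
  jm <- rjags::jags.model(textConnection(model_str), data = data,
                          n.chains = 2, quiet = TRUE,
                          inits = list(.RNG.name = "base::Mersenne-Twister",
                                       .RNG.seed = 1))
  stats::update(jm, 1500, progress.bar = "none")
  samp <- rjags::coda.samples(jm, c("tau", "sigma", "rho"), 4000,
                              progress.bar = "none")
  jags_mean <- summary(samp)$statistics[, "Mean"]
  expect_equal(blme_summary_value(fit, "tau"), unname(jags_mean["tau"]),
               tolerance = 0.05)
  expect_equal(blme_summary_value(fit, "sigma"), unname(jags_mean["sigma"]),
               tolerance = 0.05)
  expect_equal(blme_summary_value(fit, "rho"), unname(jags_mean["rho"]),
               tolerance = 0.25)
})

test_that("sampler matches the closed-form posterior in a conjugate reduction", {
  # single-timepoint data with rho fixed: integrating the subject effects
  # gives y_i ~ N(alpha0, sigma^2 + tau^2); with sigma and tau marginally
  # sampled, alpha0's posterior mean given a nearly flat prior must match
  # the weighted shrinkage formula computed from the posterior draws
  cfg <- sim_config(60, 0, alpha0 = 0.8, beta0 = 0,
                    tau = 1, rho = 0, sigma = 0.5, seed = 5)
  tab <- simulate_longitudinal(cfg)
  fit <- fit_blme(tab, blme_spec(standardize = FALSE, fix_rho = 0.01, seed = 3))
  d <- fit$draws
  ybar <- mean(tab$volume)
  n <- 60
  # closed-form conditional mean of alpha0 per draw, averaged over draws
  s0 <- 10
  cond_mean <- mean((n * ybar / (d$tau^2 + d$sigma^2)) /
                      (n / (d$tau^2 + d$sigma^2) + 1 / s0^2))
  expect_equal(mean(d$alpha0), cond_mean, tolerance = 0.02)
})

test_that("degenerate designs and scale mismatches are refused", {
  cfg <- sim_config(10, 0, 0, 0, 1, 0, 0.2, seed = 1)
  tab <- simulate_longitudinal(cfg)
  expect_error(fit_blme(tab, blme_spec()), "unidentifiable")
  expect_s3_class(fit_blme(tab, blme_spec(fix_rho = 0.01, seed = 1)),
                  "blme_posterior")
  cfg2 <- sim_config(20, c(0, 6), 0, -0.02, 1, 0.02, 0.2, seed = 2)
  tab2 <- simulate_longitudinal(cfg2)
  f_std <- fit_blme(tab2, blme_spec(seed = 1, n_warmup = 300, n_draws = 500,
                                    rhat_max = Inf))
  f_raw <- fit_blme(tab2, blme_spec(standardize = FALSE, seed = 1,
                                    n_warmup = 300, n_draws = 500,
                                    rhat_max = Inf))
  expect_error(compare_blme(f_std, f_raw), "scale mismatch")
})

test_that("variance ratio is the per-draw tau/sigma and is scale invariant", {
  cfg <- sim_config(25, c(0, 6, 12), alpha0 = 3000, beta0 = -2,
                    tau = 300, rho = 1, sigma = 60, seed = 31)
  tab <- simulate_longitudinal(cfg)
  tab_scaled <- tab
  tab_scaled$volume <- tab$volume * 3.7
  spec <- blme_spec(seed = 9, n_warmup = 500, n_draws = 800, rhat_max = Inf)
  f1 <- fit_blme(tab, spec)
  f2 <- fit_blme(volume_table(as.data.frame(tab_scaled),
                              require_positive = FALSE), spec)
  v1 <- variance_ratio(f1)
  v2 <- variance_ratio(f2)
  # standardization maps both datasets to identical inputs, so the MCMC
  # path and hence r are identical up to floating-point roundoff
  expect_equal(v1$mean, v2$mean, tolerance = 1e-6)
  expect_equal(v1$ci, v2$ci, tolerance = 1e-6)
  # comparisons of identical fits are never significant
  cmp <- compare_blme(f1, f1)
  expect_false(any(cmp$significant))
})
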
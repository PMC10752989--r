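#' Specification of the Bayesian linear mixed-effects fit
#'
#' The hierarchical model for longitudinal volumes is
#' \deqn{V_{ij} \sim N(\alpha_i + \beta_i t_{ij}, \sigma^2), \quad
#'       \alpha_i \sim N(\alpha_0, \tau^2), \quad
#'       \beta_i \sim N(\beta_0, \rho^2)}
#' with priors \eqn{\alpha_0, \beta_0 \sim N(0, 10^2)} and
#' \eqn{\sigma, \tau, \rho \sim \mathrm{Cauchy}^+(0, 5)}. Here \eqn{\tau}
#' is the between-subject variability, \eqn{\sigma} the within-subject
#' variability, and \eqn{r = \tau/\sigma} the variance ratio summarizing
#' longitudinal reliability (higher = better discrimination between
#' subjects at equal within-subject reproducibility).
#'
#' On raw volumes (thousands of mm^3) these priors would be strongly
#' informative, so by default volumes are standardized by their grand mean
#' and SD before fitting; `r` is invariant to this, and location/scale
#' summaries are reported on both scales.
#'
#' @param prior_loc_sd SD of the normal prior on alpha0 and beta0
#'   (default 10, on the fitting scale).
#' @param prior_scale scale of the half-Cauchy prior on sigma, tau, rho
#'   (default 5).
#' @param standardize center/scale volumes by the grand mean/SD before
#'   fitting (default `TRUE`).
#' @param n_chains number of MCMC chains (>= 2; default 4).
#' @param n_warmup,n_draws warmup and retained iterations per chain.
#' @param seed integer seed; chain c uses `seed + c`.
#' @param rhat_max convergence threshold on the split-Rhat diagnostic;
#'   the fit fails loudly when exceeded (default 1.01).
#' @param fix_rho optional positive value fixing the slope SD rho instead
#'   of sampling it; required for designs where every subject has a single
#'   timepoint (rho is unidentifiable there).
#' @return an object of class `blme_spec`.
#' @export
blme_spec <- function(prior_loc_sd = 10, prior_scale = 5, standardize = TRUE,
                      n_chains = 4L, n_warmup = 1500L, n_draws = 3000L,
                      seed = 1L, rhat_max = 1.01, fix_rho = NULL) {
  stopifnot(prior_loc_sd > 0, prior_scale > 0, n_chains >= 2,
            n_warmup >= 1, n_draws >= 1)
  if (!is.null(fix_rho) && fix_rho <= 0) stop("fix_rho must be positive")
  structure(list(prior_loc_sd = prior_loc_sd, prior_scale = prior_scale,
                 standardize = isTRUE(standardize),
                 n_chains = as.integer(n_chains),
                 n_warmup = as.integer(n_warmup),
                 n_draws = as.integer(n_draws),
                 seed = as.integer(seed), rhat_max = rhat_max,
                 fix_rho = fix_rho),
            class = "blme_spec")
}

#' Normalize observation times to months from each subject's baseline
#'
#' Subtracts each subject's earliest `time_months` so every subject starts
#' at t = 0; intervals are preserved.
#'
#' @param table a `volume_table`.
#' @return the table with shifted `time_months`.
#' @export
normalize_time <- function(table) {
  df <- as.data.frame(volume_table(as.data.frame(table), require_positive = FALSE))
  if (anyNA(df$time_months)) stop("time_months contains missing values; baseline undefined")
  baseline <- stats::ave(df$time_months, df$subject_id, FUN = min)
  df$time_months <- df$time_months - baseline
  volume_table(df, require_positive = FALSE)
}

# log half-Cauchy density (x > 0) with given scale
log_half_cauchy <- function(x, scale) {
  log(2) + stats::dcauchy(x, 0, scale, log = TRUE)
}

#' Exact log posterior of the hierarchical volume model
#'
#' Sum of the Gaussian likelihood over all observations, the Gaussian
#' subject-effect terms, the normal priors on the population intercept and
#' slope, and the half-Cauchy priors on the three scale parameters.
#' Returns `-Inf` (a rejected region, not an error) whenever a scale
#' parameter is non-positive, or when sigma is 0 with a non-zero residual.
#'
#' @param params list with scalars `alpha0`, `beta0`, `tau`, `sigma`,
#'   `rho` and vectors `alpha`, `beta` (one entry per subject, ordered as
#'   `sort(unique(table$subject_id))`).
#' @param table a `volume_table` (single method and ROI).
#' @param spec a [blme_spec()]; only the prior settings are used. The
#'   table is used exactly as given (no standardization is applied here).
#' @return scalar log posterior density (unnormalized).
#' @export
blme_log_posterior <- function(params, table, spec = blme_spec()) {
  with(params, {
    if (!all(is.finite(c(alpha0, beta0, tau, sigma, rho)))) return(-Inf)
    if (tau <= 0 || sigma <= 0 || rho <= 0) return(-Inf)
    df <- as.data.frame(table)
    subjects <- sort(unique(df$subject_id))
    stopifnot(length(alpha) == length(subjects), length(beta) == length(subjects))
    idx <- match(df$subject_id, subjects)
    mu <- alpha[idx] + beta[idx] * df$time_months
    sum(stats::dnorm(df$volume, mu, sigma, log = TRUE)) +
      sum(stats::dnorm(alpha, alpha0, tau, log = TRUE)) +
      sum(stats::dnorm(beta, beta0, rho, log = TRUE)) +
      stats::dnorm(alpha0, 0, spec$prior_loc_sd, log = TRUE) +
      stats::dnorm(beta0, 0, spec$prior_loc_sd, log = TRUE) +
      log_half_cauchy(sigma, spec$prior_scale) +
      log_half_cauchy(tau, spec$prior_scale) +
      log_half_cauchy(rho, spec$prior_scale)
  })
}

# split-Rhat (potential scale reduction) for a draws matrix
# (iterations x chains); NA-safe for zero-variance parameters.
split_rhat <- function(x) {
  n <- nrow(x)
  half <- floor(n / 2)
  splits <- cbind(x[seq_len(half), , drop = FALSE],
                  x[(n - half + 1):n, , drop = FALSE])
  m <- ncol(splits)
  means <- colMeans(splits)
  vars <- apply(splits, 2L, stats::var)
  w <- mean(vars)
  b <- half * stats::var(means)
  if (!is.finite(w) || w == 0) return(NA_real_)
  sqrt(((half - 1) / half * w + b / half) / w)
}

#' Fit the Bayesian linear mixed-effects model by MCMC
#'
#' Metropolis-within-Gibbs sampler: the subject effects and population
#' location parameters have Gaussian full conditionals and are updated by
#' exact Gibbs draws; the scale parameters sigma, tau, rho are updated by
#' independence Metropolis against their exact conditional shapes (an
#' inverse-gamma proposal in the centered parameterization, a
#' truncated-normal proposal in an interweaved non-centered
#' parameterization), so only the slowly varying half-Cauchy prior ratio
#' enters the acceptance probability. Interweaving the two
#' parameterizations breaks the funnel-shaped dependence between the
#' scale parameters and the subject effects that otherwise stalls
#' centered Gibbs samplers when a variance component is small. Chains
#' start from dispersed, data-informed initial values. After sampling,
#' the split-Rhat diagnostic is computed
#' for every sampled parameter and the fit fails with an explicit error
#' listing the offending parameters if any exceeds `spec$rhat_max`.
#'
#' @param table a `volume_table` holding one method and one ROI, with
#'   times normalized (see [normalize_time()]).
#' @param spec a [blme_spec()].
#' @return an object of class `blme_posterior`: list with `draws` (data
#'   frame: chain, iteration, all parameters, and `r = tau/sigma` per
#'   draw, on the fitting scale), `summaries` (mean and central 95%
#'   credible interval for alpha0, beta0, tau, sigma, rho, r on the
#'   fitting scale and, when standardized, on the raw volume scale),
#'   `rhat` (named vector over all sampled parameters), and `scale_info`.
#' @export
fit_blme <- function(table, spec = blme_spec()) {
  df <- as.data.frame(table)
  if (length(unique(df$method)) > 1L || length(unique(df$roi)) > 1L) {
    stop("fit one method and one ROI at a time (slice the table first)")
  }
  subjects <- sort(unique(df$subject_id))
  n <- length(subjects)
  if (n < 3L) stop("at least 3 subjects are required")
  idx <- match(df$subject_id, subjects)
  n_per <- tabulate(idx, n)
  multi <- sum(n_per >= 2L)
  if (multi == 0L && is.null(spec$fix_rho)) {
    stop("all subjects have a single timepoint: the slope SD rho is ",
         "unidentifiable; supply blme_spec(fix_rho = ...) to fit anyway")
  }

  y <- df$volume
  center <- 0
  scale_sd <- 1
  if (spec$standardize) {
    center <- mean(y)
    scale_sd <- stats::sd(y)
    if (!is.finite(scale_sd) || scale_sd == 0) stop("zero variance in volumes; cannot standardize")
    y <- (y - center) / scale_sd
  }
  t <- df$time_months
  N <- length(y)

  # per-subject sufficient statistics
  sum_t <- as.numeric(rowsum(t, idx))
  sum_t2 <- as.numeric(rowsum(t^2, idx))
  sum_y <- as.numeric(rowsum(y, idx))
  sum_ty <- as.numeric(rowsum(t * y, idx))
  sum_y2 <- as.numeric(rowsum(y^2, idx))

  s0 <- spec$prior_loc_sd
  a_cauchy <- spec$prior_scale
  fixed_rho <- spec$fix_rho
  n_iter <- spec$n_warmup + spec$n_draws
  par_names <- c("alpha0", "beta0", "tau", "sigma", "rho",
                 paste0("alpha[", seq_len(n), "]"),
                 paste0("beta[", seq_len(n), "]"))

  run_chain <- function(chain_id) {
    set.seed(spec$seed + chain_id)
    # data-informed, jittered inits
    subj_mean <- sum_y / n_per
    alpha_i <- subj_mean + stats::rnorm(n, 0, 0.1 * (stats::sd(subj_mean) + 0.1))
    beta_i <- stats::rnorm(n, 0, 0.05)
    alpha0 <- mean(alpha_i) + stats::rnorm(1, 0, 0.2)
    beta0 <- mean(beta_i)
    tau <- max(stats::sd(subj_mean), 0.05) * exp(stats::rnorm(1, 0, 0.3))
    sigma <- max(stats::sd(y) / 2, 0.05) * exp(stats::rnorm(1, 0, 0.3))
    rho <- if (is.null(fixed_rho)) 0.05 * exp(stats::rnorm(1, 0, 0.3)) else fixed_rho

    out <- matrix(NA_real_, nrow = spec$n_draws, ncol = length(par_names),
                  dimnames = list(NULL, par_names))

    # independence-Metropolis update of a scale parameter s given m
    # centered deviations with sum of squares ss: the conditional is
    # proportional to s^-m exp(-ss/(2 s^2)) * halfCauchy(s), i.e. an
    # inverse-gamma density in s^2 times a slowly varying prior factor.
    # Proposing s^2 from that exact inverse gamma leaves only the
    # half-Cauchy ratio in the acceptance probability (near 1).
    update_scale <- function(s, ss, m) {
      prop <- sqrt(ss / 2 / stats::rgamma(1, (m - 1) / 2))
      if (log(stats::runif(1)) <
          log_half_cauchy(prop, a_cauchy) - log_half_cauchy(s, a_cauchy)) prop else s
    }
    # Log marginal posterior of the three scales given (alpha0, beta0),
    # with the subject effects integrated out analytically: per subject
    # the marginal covariance is sigma^2 I + tau^2 11' + rho^2 t t',
    # whose determinant and quadratic form reduce to a 2x2 solve on the
    # per-subject sufficient statistics (Woodbury identity), all
    # vectorized over subjects.
    marginal_logpost <- function(tau_, sigma_, rho_) {
      if (tau_ <= 0 || sigma_ <= 0 || rho_ <= 0) return(-Inf)
      s2 <- sigma_^2
      sr <- sum_y - alpha0 * n_per - beta0 * sum_t
      str_ <- sum_ty - alpha0 * sum_t - beta0 * sum_t2
      rr <- sum_y2 - 2 * alpha0 * sum_y - 2 * beta0 * sum_ty +
        alpha0^2 * n_per + 2 * alpha0 * beta0 * sum_t + beta0^2 * sum_t2
      a <- 1 / tau_^2 + n_per / s2
      b <- sum_t / s2
      cc <- 1 / rho_^2 + sum_t2 / s2
      det_m <- a * cc - b^2
      logdet <- n_per * log(s2) + log(tau_^2) + log(rho_^2) + log(det_m)
      w1 <- sr / s2
      w2 <- str_ / s2
      quad <- rr / s2 - (cc * w1^2 - 2 * b * w1 * w2 + a * w2^2) / det_m
      sum(-0.5 * (logdet + quad)) +
        log_half_cauchy(tau_, a_cauchy) + log_half_cauchy(sigma_, a_cauchy) +
        log_half_cauchy(rho_, a_cauchy)
    }
    # non-centered counterpart: with the subject effects held as
    # standardized deviations, the likelihood is Gaussian in the scale
    # (coefficient of a known regressor), so propose from that exact
    # truncated-normal conditional; again only the half-Cauchy prior
    # ratio remains in the acceptance probability.
    update_scale_nc <- function(s, src, scc) {
      if (scc <= 0) return(s)
      m <- src / scc
      sd_p <- sigma / sqrt(scc)
      u <- stats::runif(1, stats::pnorm(0, m, sd_p), 1)
      prop <- stats::qnorm(u, m, sd_p)
      if (!is.finite(prop) || prop <= 0) return(s)
      if (log(stats::runif(1)) <
          log_half_cauchy(prop, a_cauchy) - log_half_cauchy(s, a_cauchy)) prop else s
    }

    lp_marg <- marginal_logpost(tau, sigma, rho)
    step <- 0.15
    acc <- 0L

    for (it in seq_len(n_iter)) {
      # Collapsed update of the scales: joint lognormal random walk on
      # (tau, sigma, rho) targeting their marginal posterior given
      # (alpha0, beta0) with the subject effects integrated out; the
      # effects are then redrawn jointly from their exact bivariate
      # Gaussian conditionals, so the move is a valid partially collapsed
      # draw and is immune to the funnel between small variance
      # components and their subject effects.
      for (rep_mh in 1:3) {
        eps <- stats::rnorm(if (is.null(fixed_rho)) 3L else 2L, 0, step)
        tau_p <- tau * exp(eps[1L])
        sigma_p <- sigma * exp(eps[2L])
        rho_p <- if (is.null(fixed_rho)) rho * exp(eps[3L]) else rho
        lp_prop <- marginal_logpost(tau_p, sigma_p, rho_p)
        jac <- sum(log(c(tau_p, sigma_p, if (is.null(fixed_rho)) rho_p)) -
                     log(c(tau, sigma, if (is.null(fixed_rho)) rho)))
        if (log(stats::runif(1)) < lp_prop - lp_marg + jac) {
          tau <- tau_p; sigma <- sigma_p; rho <- rho_p
          lp_marg <- lp_prop
          acc <- acc + 1L
        }
      }
      if (it <= spec$n_warmup && it %% 50L == 0L) {
        step <- min(max(step * exp(acc / 150 - 0.30), 1e-3), 2)
        acc <- 0L
      }
      # (alpha_i, beta_i) | . : joint bivariate Gaussian draw per subject
      # (closed-form 2x2 Cholesky, vectorized over subjects)
      p11 <- n_per / sigma^2 + 1 / tau^2
      p22 <- sum_t2 / sigma^2 + 1 / rho^2
      p12 <- sum_t / sigma^2
      det_p <- p11 * p22 - p12^2
      b1 <- sum_y / sigma^2 + alpha0 / tau^2
      b2 <- sum_ty / sigma^2 + beta0 / rho^2
      m1 <- (p22 * b1 - p12 * b2) / det_p
      m2 <- (p11 * b2 - p12 * b1) / det_p
      v11 <- p22 / det_p
      v12 <- -p12 / det_p
      v22 <- p11 / det_p
      z1 <- stats::rnorm(n)
      z2 <- stats::rnorm(n)
      alpha_i <- m1 + sqrt(v11) * z1
      beta_i <- m2 + (v12 / sqrt(v11)) * z1 + sqrt(v22 - v12^2 / v11) * z2
      # alpha0, beta0 | .
      prec0 <- n / tau^2 + 1 / s0^2
      alpha0 <- stats::rnorm(1, sum(alpha_i) / tau^2 / prec0, sqrt(1 / prec0))
      prec0 <- n / rho^2 + 1 / s0^2
      beta0 <- stats::rnorm(1, sum(beta_i) / rho^2 / prec0, sqrt(1 / prec0))
      # Scale parameters, second pass: independence Metropolis on the
      # centered conditionals, interweaved with non-centered updates in
      # which the subject effects are held as standardized deviations and
      # the scale becomes a regression coefficient in the likelihood.
      resid <- y - alpha_i[idx] - beta_i[idx] * t
      sigma <- update_scale(sigma, sum(resid^2), N)
      tau <- update_scale(tau, sum((alpha_i - alpha0)^2), n)
      if (is.null(fixed_rho)) {
        rho <- update_scale(rho, sum((beta_i - beta0)^2), n)
      }
      a_nc <- (alpha_i - alpha0) / tau
      r0 <- y - beta_i[idx] * t - alpha0
      tau <- update_scale_nc(tau, sum(r0 * a_nc[idx]), sum(a_nc[idx]^2))
      # alpha0 is a plain regression intercept given the standardized
      # deviations: exact Gaussian conditional
      prec0 <- N / sigma^2 + 1 / s0^2
      m0 <- sum(y - beta_i[idx] * t - tau * a_nc[idx]) / sigma^2 / prec0
      alpha0 <- stats::rnorm(1, m0, sqrt(1 / prec0))
      alpha_i <- alpha0 + tau * a_nc
      b_nc <- (beta_i - beta0) / rho
      if (is.null(fixed_rho)) {
        r0 <- y - alpha_i[idx] - beta0 * t
        cvec <- b_nc[idx] * t
        rho <- update_scale_nc(rho, sum(r0 * cvec), sum(cvec^2))
      }
      # beta0 is redrawn in the non-centered parameterization even when
      # rho is fixed: in degenerate designs (e.g. t identically 0) the
      # centered conditional collapses to a tiny-step random walk around
      # the subject slopes, while this one draws from the full
      # data-plus-prior conditional directly
      prec0 <- sum(t^2) / sigma^2 + 1 / s0^2
      m0 <- sum(t * (y - alpha_i[idx] - rho * b_nc[idx] * t)) / sigma^2 / prec0
      beta0 <- stats::rnorm(1, m0, sqrt(1 / prec0))
      beta_i <- beta0 + rho * b_nc
      # refresh the cached marginal log posterior (alpha0/beta0 and the
      # scales may all have moved since the collapsed step)
      lp_marg <- marginal_logpost(tau, sigma, rho)
      if (it > spec$n_warmup) {
        out[it - spec$n_warmup, ] <- c(alpha0, beta0, tau, sigma, rho,
                                       alpha_i, beta_i)
      }
    }
    out
  }

  restore <- set_local_seed(spec$seed)
  chains <- lapply(seq_len(spec$n_chains), run_chain)
  restore()

  rhat <- vapply(par_names, function(p) {
    split_rhat(sapply(chains, function(ch) ch[, p]))
  }, numeric(1))
  if (!is.null(fixed_rho)) rhat["rho"] <- NA_real_
  bad <- names(rhat)[!is.na(rhat) & rhat > spec$rhat_max]
  if (length(bad) > 0L) {
    stop("MCMC did not converge: split-Rhat > ", spec$rhat_max, " for ",
         paste(sprintf("%s (%.3f)", bad, rhat[bad]), collapse = ", "),
         "; increase n_warmup/n_draws")
  }

  draws <- do.call(rbind, lapply(seq_along(chains), function(c_id) {
    data.frame(chain = c_id, iteration = seq_len(spec$n_draws),
               chains[[c_id]], check.names = FALSE)
  }))
  draws$r <- draws$tau / draws$sigma

  summarize <- function(v) {
    ci <- stats::quantile(v, c(0.025, 0.975), names = FALSE, type = 7)
    c(mean = mean(v), ci_low = ci[1L], ci_high = ci[2L])
  }
  core <- c("alpha0", "beta0", "tau", "sigma", "rho", "r")
  summ <- as.data.frame(t(vapply(core, function(p) summarize(draws[[p]]),
                                 numeric(3))))
  summ$parameter <- core
  summ$rhat <- c(rhat[core[1:5]], NA_real_)
  summ <- summ[, c("parameter", "mean", "ci_low", "ci_high", "rhat")]
  rownames(summ) <- NULL
  if (spec$standardize) {
    raw <- summ
    scale_map <- c(alpha0 = scale_sd, beta0 = scale_sd, tau = scale_sd,
                   sigma = scale_sd, rho = scale_sd, r = 1)
    shift_map <- c(alpha0 = center, beta0 = 0, tau = 0, sigma = 0, rho = 0, r = 0)
    for (col in c("mean", "ci_low", "ci_high")) {
      raw[[col]] <- summ[[col]] * scale_map[summ$parameter] +
        shift_map[summ$parameter]
    }
    summ_raw <- raw
  } else {
    summ_raw <- summ
  }

  structure(list(draws = draws, summaries = summ, summaries_raw = summ_raw,
                 rhat = rhat,
                 scale_info = list(standardized = spec$standardize,
                                   center = center, scale = scale_sd),
                 n_subjects = n, n_obs = N, spec = spec),
            class = "blme_posterior")
}

#' @export
print.blme_posterior <- function(x, ...) {
  cat(sprintf("Bayesian LME posterior: %d subjects, %d observations, %d chains x %d draws\n",
              x$n_subjects, x$n_obs, x$spec$n_chains, x$spec$n_draws))
  cat(if (x$scale_info$standardized) "fitting scale: standardized volumes\n"
      else "fitting scale: raw volumes\n")
  print(format(x$summaries, digits = 4), ...)
  invisible(x)
}

#' Posterior variance ratio r = tau / sigma
#'
#' The between- over within-subject SD ratio computed per posterior draw
#' and then summarized (posterior mean and central 95% credible interval).
#' Invariant to any common rescaling of the volumes, so identical whether
#' the model was fitted on raw or standardized data.
#'
#' @param post a `blme_posterior`.
#' @return list with `mean` and `ci` (length-2 vector).
#' @export
variance_ratio <- function(post) {
  stopifnot(inherits(post, "blme_posterior"))
  r <- post$draws$r
  list(mean = mean(r),
       ci = stats::quantile(r, c(0.025, 0.975), names = FALSE, type = 7))
}

#' Compare two fitted models by the CI-overlap rule
#'
#' Applies [ci_overlap_significant()] to the posterior summaries of the
#' variance ratio r, the between-subject variability tau, and the
#' within-subject variability sigma of two fits: a pair is significantly
#' different when neither posterior mean lies inside the other's 95%
#' credible interval. Both fits must be on the same scale (both
#' standardized or both raw).
#'
#' @param post_a,post_b `blme_posterior` objects.
#' @param label_a,label_b names used in the output table.
#' @return data frame with one row per quantity (`r`, `tau`, `sigma`):
#'   estimates, intervals, and the significance decision.
#' @export
compare_blme <- function(post_a, post_b, label_a = "A", label_b = "B") {
  stopifnot(inherits(post_a, "blme_posterior"), inherits(post_b, "blme_posterior"))
  if (!identical(post_a$scale_info$standardized, post_b$scale_info$standardized)) {
    stop("scale mismatch: one posterior is standardized and the other is not")
  }
  quantities <- c("r", "tau", "sigma")
  rows <- lapply(quantities, function(q) {
    sa <- post_a$summaries[post_a$summaries$parameter == q, ]
    sb <- post_b$summaries[post_b$summaries$parameter == q, ]
    data.frame(quantity = q,
               est_a = sa$mean, ci_low_a = sa$ci_low, ci_high_a = sa$ci_high,
               est_b = sb$mean, ci_low_b = sb$ci_low, ci_high_b = sb$ci_high,
               significant = ci_overlap_significant(
                 sa$mean, c(sa$ci_low, sa$ci_high),
                 sb$mean, c(sb$ci_low, sb$ci_high)))
  })
  out <- do.call(rbind, rows)
  attr(out, "labels") <- c(label_a, label_b)
  out
}
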
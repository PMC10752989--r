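#' Generative configuration for longitudinal volume trajectories
#'
#' Parameterizes the hierarchical model under which longitudinal tables are
#' simulated: subject intercepts alpha_i ~ N(alpha0, tau^2), subject slopes
#' beta_i ~ N(beta0, rho^2), and observations V = alpha_i + beta_i * t +
#' eps with eps ~ N(0, sigma^2), t in months from baseline.
#'
#' @param n_subjects number of subjects (>= 1).
#' @param timepoints_months strictly increasing visit times in months;
#'   first element must be 0 (baseline).
#' @param alpha0 population mean intercept (volume units).
#' @param beta0 population mean slope (volume units per month).
#' @param tau between-subject intercept SD (>= 0).
#' @param rho between-subject slope SD (>= 0).
#' @param sigma within-subject residual SD (>= 0).
#' @param seed integer RNG seed; identical configs give bit-identical tables.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_subjects, timepoints_months, alpha0, beta0,
                       tau, rho, sigma, seed = 1L) {
  check_scalar <- function(x, name, min = -Inf) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
      stop("invalid field '", name, "': must be a finite numeric scalar")
    }
    if (x < min) stop("invalid field '", name, "': must be >= ", min)
  }
  check_scalar(n_subjects, "n_subjects", min = 1)
  if (n_subjects != round(n_subjects)) stop("invalid field 'n_subjects': must be an integer")
  if (!is.numeric(timepoints_months) || length(timepoints_months) < 1L ||
      anyNA(timepoints_months)) {
    stop("invalid field 'timepoints_months': must be a non-empty numeric vector")
  }
  if (timepoints_months[1L] != 0) {
    stop("invalid field 'timepoints_months': first timepoint must be 0 (baseline)")
  }
  if (length(timepoints_months) > 1L && any(diff(timepoints_months) <= 0)) {
    stop("invalid field 'timepoints_months': must be strictly increasing")
  }
  check_scalar(alpha0, "alpha0")
  check_scalar(beta0, "beta0")
  check_scalar(tau, "tau", min = 0)
  check_scalar(rho, "rho", min = 0)
  check_scalar(sigma, "sigma", min = 0)
  check_scalar(seed, "seed")
  structure(list(n_subjects = as.integer(n_subjects),
                 timepoints_months = as.numeric(timepoints_months),
                 alpha0 = alpha0, beta0 = beta0,
                 tau = tau, rho = rho, sigma = sigma,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate longitudinal volume trajectories
#'
#' Draws per-subject intercepts and slopes once, then emits one observation
#' per subject x timepoint under the exact hierarchical generative law of
#' [sim_config()]. Subject-level effects are drawn before any residuals, in
#' subject order, so adding timepoints to a config leaves the subject
#' effects unchanged. No positivity truncation is applied: the generative
#' law is Gaussian, and configs on a standardized scale (alpha0 near 0)
#' produce non-positive volumes by design.
#'
#' @param config a [sim_config()].
#' @param method,roi labels stamped on every record.
#' @return a `volume_table` with `n_subjects * length(timepoints_months)`
#'   rows; sessions are labelled `m<time>`.
#' @export
simulate_longitudinal <- function(config, method = "simulated",
                                  roi = "hippocampus_L") {
  if (!inherits(config, "sim_config")) {
    config <- do.call(sim_config, config)
  }
  n <- config$n_subjects
  tp <- config$timepoints_months
  withr_seed <- set_local_seed(config$seed)
  on.exit(withr_seed(), add = TRUE)
  alpha_i <- stats::rnorm(n, config$alpha0, config$tau)
  beta_i <- stats::rnorm(n, config$beta0, config$rho)
  subj <- rep(seq_len(n), each = length(tp))
  t <- rep(tp, times = n)
  v <- alpha_i[subj] + beta_i[subj] * t + stats::rnorm(length(t), 0, config$sigma)
  volume_table(data.frame(
    subject_id = sprintf("S%04d", subj),
    method = method, roi = roi,
    session = sprintf("m%g", t),
    time_months = t, volume = v,
    stringsAsFactors = FALSE
  ), require_positive = FALSE)
}

#' Simulate a two-session test-retest volume table
#'
#' Each subject gets a true volume u_i ~ N(mu, between_sd^2); the "test"
#' and "retest" sessions observe u_i plus independent N(0, within_sd^2)
#' noise. Non-positive draws are rejected and redrawn (volumes are
#' physical quantities); the rejection count is attached as attribute
#' `n_rejected` and surfaced with a message when non-zero. The analytic
#' intraclass correlation of this generator is
#' `between_sd^2 / (between_sd^2 + within_sd^2)`.
#'
#' @param n_subjects number of subjects.
#' @param mu population mean volume (> 0, e.g. mm^3).
#' @param between_sd,within_sd between-/within-subject SDs (>= 0).
#' @param seed integer RNG seed.
#' @param method,roi labels stamped on every record.
#' @return a `volume_table` with sessions `"test"` and `"retest"`.
#' @export
simulate_testretest <- function(n_subjects, mu, between_sd, within_sd,
                                seed = 1L, method = "simulated",
                                roi = "hippocampus_L") {
  if (n_subjects < 1) stop("n_subjects must be >= 1")
  if (mu <= 0) stop("mu must be positive")
  if (between_sd < 0 || within_sd < 0) stop("SD parameters must be non-negative")
  p_neg <- stats::pnorm(0, mean = mu, sd = sqrt(between_sd^2 + within_sd^2))
  if (p_neg > 0.01) {
    warning(sprintf(
      "parameters imply %.1f%% probability of a non-positive volume draw; heavy rejection resampling distorts the generative law",
      100 * p_neg))
  }
  restore <- set_local_seed(seed)
  on.exit(restore(), add = TRUE)
  n_rejected <- 0L
  draw_pos <- function(n, mean, sd) {
    x <- stats::rnorm(n, mean, sd)
    while (any(bad <- x <= 0)) {
      n_rejected <<- n_rejected + sum(bad)
      x[bad] <- stats::rnorm(sum(bad), mean[bad], if (length(sd) > 1L) sd[bad] else sd)
    }
    x
  }
  u <- draw_pos(n_subjects, rep(mu, n_subjects), between_sd)
  v_test <- draw_pos(n_subjects, u, within_sd)
  v_retest <- draw_pos(n_subjects, u, within_sd)
  tab <- volume_table(data.frame(
    subject_id = rep(sprintf("S%04d", seq_len(n_subjects)), times = 2L),
    method = method, roi = roi,
    session = rep(c("test", "retest"), each = n_subjects),
    time_months = 0,
    volume = c(v_test, v_retest),
    stringsAsFactors = FALSE
  ))
  attr(tab, "n_rejected") <- n_rejected
  if (n_rejected > 0L) {
    message("simulate_testretest: ", n_rejected, " non-positive draw(s) rejected and redrawn")
  }
  tab
}

#' Simulate paired manual/predicted volumes for an accuracy study
#'
#' Ground-truth volumes are drawn from N(gt_mean, gt_sd^2) truncated to be
#' positive; the automated method observes
#' `v_pred = v_gt * (1 + (bias_pct + eta)/100)` with eta ~ N(0,
#' noise_pct^2), i.e. a method with systematic relative bias `bias_pct`
#' percent and relative imprecision `noise_pct` percent. Downstream volume
#' percentage errors then have mean ~ bias_pct and SD ~ noise_pct.
#'
#' @param n_subjects number of subjects.
#' @param gt_mean,gt_sd mean and SD of the ground-truth volumes (gt_mean > 0).
#' @param bias_pct systematic percent bias of the predicted volumes.
#' @param noise_pct SD of the percent error (>= 0).
#' @param seed integer RNG seed.
#' @param roi label stamped on every record.
#' @return a `volume_table` with methods `"manual"` and `"predicted"`,
#'   single session `"s1"`; rejection count in attribute `n_rejected`.
#' @export
simulate_accuracy <- function(n_subjects, gt_mean, gt_sd, bias_pct,
                              noise_pct, seed = 1L, roi = "hippocampus_L") {
  if (n_subjects < 1) stop("n_subjects must be >= 1")
  if (gt_mean <= 0) stop("gt_mean must be positive")
  if (gt_sd < 0 || noise_pct < 0) stop("gt_sd and noise_pct must be non-negative")
  if (stats::pnorm(0, gt_mean, gt_sd) > 0.01) {
    warning("parameters imply >1% probability of non-positive ground-truth draws")
  }
  restore <- set_local_seed(seed)
  on.exit(restore(), add = TRUE)
  n_rejected <- 0L
  v_gt <- stats::rnorm(n_subjects, gt_mean, gt_sd)
  while (any(bad <- v_gt <= 0)) {
    n_rejected <- n_rejected + sum(bad)
    v_gt[bad] <- stats::rnorm(sum(bad), gt_mean, gt_sd)
  }
  eta <- stats::rnorm(n_subjects, 0, noise_pct)
  v_pred <- v_gt * (1 + (bias_pct + eta) / 100)
  while (any(bad <- v_pred <= 0)) {
    n_rejected <- n_rejected + sum(bad)
    eta[bad] <- stats::rnorm(sum(bad), 0, noise_pct)
    v_pred[bad] <- v_gt[bad] * (1 + (bias_pct + eta[bad]) / 100)
  }
  ids <- sprintf("S%04d", seq_len(n_subjects))
  tab <- volume_table(data.frame(
    subject_id = rep(ids, times = 2L),
    method = rep(c("manual", "predicted"), each = n_subjects),
    roi = roi, session = "s1", time_months = 0,
    volume = c(v_gt, v_pred),
    stringsAsFactors = FALSE
  ))
  attr(tab, "n_rejected") <- n_rejected
  if (n_rejected > 0L) {
    message("simulate_accuracy: ", n_rejected, " non-positive draw(s) rejected and redrawn")
  }
  tab
}

# seed the session RNG locally and return a restorer for the previous state
set_local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(as.integer(seed))
  function() {
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
}
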
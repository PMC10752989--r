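#' Accuracy study: percent errors, correlations and method comparisons
#'
#' For each non-reference method and ROI, computes the per-subject volume
#' percentage errors against the ground-truth method, their summary table
#' (median, mean, quartiles, SD), and the Pearson correlation with the
#' ground-truth volumes plus its interpretation band. Every pair of
#' non-reference methods is then compared with the full battery: the
#' normality-gated paired location test on the percent errors (absolute
#' values by default, matching how systematic error magnitude is
#' compared), the F-test on the percent-error variances (precision), and
#' the Fisher z-test on the two correlations (accuracy).
#'
#' Subjects missing from either member of a (method, ground truth) pair
#' are excluded with a warning and listed in the report.
#'
#' @param table a `volume_table` with one session per subject and at least
#'   two methods.
#' @param gt_method label of the ground-truth (reference) method.
#' @param alpha significance level for the comparison tests (default 0.01).
#' @param alpha_normality level of the normality gate (default 0.05).
#' @param absolute_vpe compare |VPE| in the location test (default `TRUE`).
#' @return list of class `accuracy_report` with elements `per_method`
#'   (summary + correlation table), `vpe_values` (long per-subject
#'   errors), `comparisons` (tidy test table), `excluded` (subjects
#'   dropped per method/ROI).
#' @export
run_accuracy <- function(table, gt_method = "manual", alpha = 0.01,
                         alpha_normality = 0.05, absolute_vpe = TRUE) {
  df <- as.data.frame(table)
  if (!gt_method %in% df$method) stop("ground-truth method '", gt_method, "' not in table")
  methods <- setdiff(unique(df$method), gt_method)
  if (length(methods) == 0L) stop("no comparison method in table")
  rois <- unique(df$roi)

  per_method <- list()
  vpe_values <- list()
  excluded <- list()
  for (roi in rois) {
    gt <- df[df$method == gt_method & df$roi == roi, ]
    for (m in methods) {
      pred <- df[df$method == m & df$roi == roi, ]
      common <- intersect(gt$subject_id, pred$subject_id)
      dropped <- setdiff(union(gt$subject_id, pred$subject_id), common)
      if (length(dropped) > 0L) {
        warning(sprintf("accuracy (%s, %s): excluding %d unmatched subject(s)",
                        m, roi, length(dropped)))
        excluded[[paste(m, roi, sep = "/")]] <- dropped
      }
      if (length(common) < 3L) stop("fewer than 3 matched subjects for ", m, " / ", roi)
      v_gt <- gt$volume[match(common, gt$subject_id)]
      v_pred <- pred$volume[match(common, pred$subject_id)]
      err <- vpe(v_pred, v_gt)
      cc <- pearson_cc(v_pred, v_gt)
      s <- vpe_summary(err)
      per_method[[paste(m, roi, sep = "/")]] <- cbind(
        data.frame(method = m, roi = roi), s,
        data.frame(cc = cc$r, cc_band = cc$band))
      vpe_values[[paste(m, roi, sep = "/")]] <- data.frame(
        method = m, roi = roi, subject_id = common, vpe = err)
    }
  }
  per_method <- do.call(rbind, c(per_method, list(make.row.names = FALSE)))
  vpe_values <- do.call(rbind, c(vpe_values, list(make.row.names = FALSE)))

  comparisons <- list()
  if (length(methods) >= 2L) {
    pairs <- utils::combn(methods, 2L, simplify = FALSE)
    for (roi in rois) {
      for (pr in pairs) {
        ea <- vpe_values[vpe_values$method == pr[1L] & vpe_values$roi == roi, ]
        eb <- vpe_values[vpe_values$method == pr[2L] & vpe_values$roi == roi, ]
        common <- intersect(ea$subject_id, eb$subject_id)
        va <- ea$vpe[match(common, ea$subject_id)]
        vb <- eb$vpe[match(common, eb$subject_id)]
        loc <- if (absolute_vpe) {
          paired_location_test(abs(va), abs(vb), alpha, alpha_normality)
        } else {
          paired_location_test(va, vb, alpha, alpha_normality)
        }
        ftest <- variance_f_test(va, vb, alpha)
        ra <- per_method[per_method$method == pr[1L] & per_method$roi == roi, ]
        rb <- per_method[per_method$method == pr[2L] & per_method$roi == roi, ]
        fz <- fisher_z_test(ra$cc, ra$n, rb$cc, rb$n, alpha)
        comparisons[[paste(roi, pr[1L], pr[2L], sep = "/")]] <- data.frame(
          roi = roi, method_a = pr[1L], method_b = pr[2L],
          test = c(loc$test_name, ftest$test_name, fz$test_name),
          statistic = c(loc$statistic, ftest$statistic, fz$statistic),
          p_value = c(loc$p_value, ftest$p_value, fz$p_value),
          significant = c(loc$significant, ftest$significant, fz$significant))
      }
    }
  }
  comparisons <- if (length(comparisons) > 0L) {
    do.call(rbind, c(comparisons, list(make.row.names = FALSE)))
  } else NULL

  structure(list(per_method = per_method, vpe_values = vpe_values,
                 comparisons = comparisons, excluded = excluded,
                 gt_method = gt_method, alpha = alpha),
            class = "accuracy_report")
}

#' Test-retest study: ICC, percent differences and method comparisons
#'
#' Requires exactly two sessions per (subject, method, ROI). For each
#' method and ROI, computes the consistency ICC with its 95% CI and
#' reliability band, per-subject volume percentage differences with their
#' median and interquartile range, and the share of subjects whose VPD is
#' below `vpd_threshold` percent. Pairs of methods are compared with the
#' gated location test on VPD and the CI-overlap decision on the ICCs.
#'
#' @param table a `volume_table` with two sessions per key.
#' @param alpha significance level for the location tests (default 0.01).
#' @param alpha_icc level of the ICC confidence interval (default 0.05,
#'   i.e. 95% CI).
#' @param alpha_normality level of the normality gate.
#' @param vpd_threshold reporting threshold in percent (default 2).
#' @return list of class `testretest_report` with `per_method`,
#'   `vpd_values`, `icc` (named list of `icc_result`), `comparisons`.
#' @export
run_testretest <- function(table, alpha = 0.01, alpha_icc = 0.05,
                           alpha_normality = 0.05, vpd_threshold = 2) {
  df <- as.data.frame(table)
  counts <- table(paste(df$subject_id, df$method, df$roi, sep = "/"))
  bad <- names(counts)[counts != 2L]
  if (length(bad) > 0L) {
    stop("each (subject, method, roi) needs exactly 2 sessions; offending key(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  methods <- unique(df$method)
  rois <- unique(df$roi)
  per_method <- list()
  vpd_values <- list()
  icc_list <- list()
  for (roi in rois) {
    for (m in methods) {
      mat <- pivot_sessions(df, method = m, roi = roi)
      icc <- icc_consistency(mat, alpha = alpha_icc)
      d <- vpd(mat[, 1L], mat[, 2L])
      q <- stats::quantile(d, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
      key <- paste(m, roi, sep = "/")
      icc_list[[key]] <- icc
      per_method[[key]] <- data.frame(
        method = m, roi = roi, n_subjects = nrow(mat),
        icc = icc$estimate, icc_ci_low = icc$ci_low, icc_ci_high = icc$ci_high,
        icc_band = icc$band,
        vpd_median = q[2L], vpd_p25 = q[1L], vpd_p75 = q[3L],
        vpd_share_below = mean(d < vpd_threshold))
      vpd_values[[key]] <- data.frame(method = m, roi = roi,
                                      subject_id = rownames(mat), vpd = d)
    }
  }
  per_method <- do.call(rbind, c(per_method, list(make.row.names = FALSE)))
  vpd_values <- do.call(rbind, c(vpd_values, list(make.row.names = FALSE)))

  comparisons <- list()
  if (length(methods) >= 2L) {
    pairs <- utils::combn(methods, 2L, simplify = FALSE)
    for (roi in rois) {
      for (pr in pairs) {
        da <- vpd_values[vpd_values$method == pr[1L] & vpd_values$roi == roi, ]
        db <- vpd_values[vpd_values$method == pr[2L] & vpd_values$roi == roi, ]
        common <- intersect(da$subject_id, db$subject_id)
        loc <- paired_location_test(da$vpd[match(common, da$subject_id)],
                                    db$vpd[match(common, db$subject_id)],
                                    alpha, alpha_normality)
        ia <- icc_list[[paste(pr[1L], roi, sep = "/")]]
        ib <- icc_list[[paste(pr[2L], roi, sep = "/")]]
        icc_sig <- ci_overlap_significant(ia$estimate, c(ia$ci_low, ia$ci_high),
                                          ib$estimate, c(ib$ci_low, ib$ci_high))
        comparisons[[paste(roi, pr[1L], pr[2L], sep = "/")]] <- data.frame(
          roi = roi, method_a = pr[1L], method_b = pr[2L],
          test = c(paste0(loc$test_name, " on VPD"), "ICC CI-overlap"),
          statistic = c(loc$statistic, NA_real_),
          p_value = c(loc$p_value, NA_real_),
          significant = c(loc$significant, icc_sig))
      }
    }
  }
  comparisons <- if (length(comparisons) > 0L) {
    do.call(rbind, c(comparisons, list(make.row.names = FALSE)))
  } else NULL

  structure(list(per_method = per_method, vpd_values = vpd_values,
                 icc = icc_list, comparisons = comparisons,
                 alpha = alpha, vpd_threshold = vpd_threshold),
            class = "testretest_report")
}

#' Longitudinal study: hierarchical model fits and comparisons
#'
#' Normalizes times to each subject's baseline, fits the Bayesian linear
#' mixed-effects model per method and ROI, and applies the CI-overlap
#' decision rule to every pair of methods for the variance ratio r, the
#' between-subject variability tau, and the within-subject variability
#' sigma.
#'
#' @param table a `volume_table` with longitudinal sessions.
#' @param spec a [blme_spec()] applied to every fit.
#' @return list of class `longitudinal_report` with `fits` (named
#'   `blme_posterior` list), `per_method` (summary table), `comparisons`.
#' @export
run_longitudinal <- function(table, spec = blme_spec()) {
  df <- as.data.frame(normalize_time(table))
  methods <- unique(df$method)
  rois <- unique(df$roi)
  fits <- list()
  per_method <- list()
  for (roi in rois) {
    for (m in methods) {
      slice <- volume_table(df[df$method == m & df$roi == roi, ],
                            require_positive = FALSE)
      fit <- fit_blme(slice, spec)
      key <- paste(m, roi, sep = "/")
      fits[[key]] <- fit
      vr <- variance_ratio(fit)
      s <- fit$summaries
      grab <- function(p, col) s[s$parameter == p, col]
      per_method[[key]] <- data.frame(
        method = m, roi = roi,
        r_mean = vr$mean, r_ci_low = vr$ci[1L], r_ci_high = vr$ci[2L],
        tau_mean = grab("tau", "mean"), tau_ci_low = grab("tau", "ci_low"),
        tau_ci_high = grab("tau", "ci_high"),
        sigma_mean = grab("sigma", "mean"), sigma_ci_low = grab("sigma", "ci_low"),
        sigma_ci_high = grab("sigma", "ci_high"),
        max_rhat = max(fit$rhat, na.rm = TRUE))
    }
  }
  per_method <- do.call(rbind, c(per_method, list(make.row.names = FALSE)))

  comparisons <- list()
  if (length(methods) >= 2L) {
    pairs <- utils::combn(methods, 2L, simplify = FALSE)
    for (roi in rois) {
      for (pr in pairs) {
        cmp <- compare_blme(fits[[paste(pr[1L], roi, sep = "/")]],
                            fits[[paste(pr[2L], roi, sep = "/")]],
                            label_a = pr[1L], label_b = pr[2L])
        cmp <- cbind(data.frame(roi = roi, method_a = pr[1L], method_b = pr[2L]),
                     cmp)
        comparisons[[paste(roi, pr[1L], pr[2L], sep = "/")]] <- cmp
      }
    }
  }
  comparisons <- if (length(comparisons) > 0L) {
    do.call(rbind, c(comparisons, list(make.row.names = FALSE)))
  } else NULL

  structure(list(fits = fits, per_method = per_method,
                 comparisons = comparisons, spec = spec),
            class = "longitudinal_report")
}

#' Write a study report to disk as CSV tables plus a JSON summary
#'
#' Every rectangular element of the report becomes `<prefix>_<name>.csv`;
#' a JSON file carries the same tables together with a provenance block
#' (package version, seed where available, parameters). Posterior draws of
#' longitudinal fits are written as one CSV per fit (chain and iteration
#' columns first). Output is deterministic: identical reports produce
#' byte-identical files.
#'
#' @param report a report object from [run_accuracy()],
#'   [run_testretest()] or [run_longitudinal()].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix (default from the report class).
#' @return invisibly, the paths written.
#' @export
write_report <- function(report, dir, prefix = class(report)[1L]) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  json <- list(provenance = list(
    package = "volrely",
    version = as.character(utils::packageVersion("volrely"))))
  for (name in names(report)) {
    el <- report[[name]]
    if (is.data.frame(el)) {
      p <- file.path(dir, paste0(prefix, "_", name, ".csv"))
      utils::write.csv(el, p, row.names = FALSE, quote = FALSE)
      paths <- c(paths, p)
      json[[name]] <- el
    } else if (name == "spec" || name == "alpha" || name == "vpd_threshold" ||
               name == "gt_method") {
      json$provenance[[name]] <- if (inherits(el, "blme_spec")) unclass(el) else el
    } else if (name == "excluded" && length(el) > 0L) {
      json$excluded <- el
    } else if (name == "icc") {
      json$icc <- lapply(el, unclass)
    } else if (name == "fits") {
      for (key in names(el)) {
        p <- file.path(dir, paste0(prefix, "_draws_",
                                   gsub("[^A-Za-z0-9_.-]", "-", key), ".csv"))
        utils::write.csv(el[[key]]$draws, p, row.names = FALSE, quote = FALSE)
        paths <- c(paths, p)
      }
      json$rhat <- lapply(el, function(f) f$rhat)
      json$scale_info <- lapply(el, function(f) f$scale_info)
    }
  }
  jp <- file.path(dir, paste0(prefix, "_report.json"))
  jsonlite::write_json(json, jp, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  paths <- c(paths, jp)
  invisible(paths)
}
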
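#' Compute the per-eye metrics table for a cohort of exams
#'
#' For each exam: mean sensitivity (dB and dB deg^2), VTOT from both
#' engines (the thin-plate-spline surface is fitted once per exam and
#' integrated under both the planar and the solid-angle element), and
#' BCEA95 where fixation samples exist. Covariates, if supplied, are merged
#' by (patient, eye).
#'
#' @param exams List of [mp_exam()] objects.
#' @param covariates Optional covariate data.frame (see
#'   [read_covariate_table()]).
#' @param lambda TPS smoothing (default 0).
#' @param resolution Quadrature resolution in degrees (default 0.05).
#' @param check_convergence Report quadrature convergence per eye.
#' @return data.frame with one row per eye: `patient_id`, `eye`, `ms_db`,
#'   `ms_dbdeg2`, `vtot_cart_dbdeg2`, `vtot_polar_dbsr`,
#'   `vtot_polar_dbdeg2`, `bcea95_deg2`, `log10_bcea95`, plus covariates.
#' @export
compute_metrics <- function(exams, covariates = NULL, lambda = 0,
                            resolution = 0.05, check_convergence = FALSE) {
  stopifnot(length(exams) > 0)
  rows <- lapply(exams, function(e) {
    issues <- validate_exam(e)
    issues <- issues[issues$code != "no_fixation", , drop = FALSE]
    if (nrow(issues) > 0)
      stop(sprintf("exam %s/%s fails validation: %s", e$patient_id, e$eye,
                   paste(issues$code, collapse = ", ")), call. = FALSE)
    area <- convex_hull_area(e$points)
    domain <- integration_domain("convex_hull", points = e$points)
    wt <- domain_weights(domain, resolution)
    interp <- fit_tps(e$points, e$thresholds, lambda = lambda)
    f <- predict(interp, cbind(wt$x, wt$y))
    v_cart <- sum(f * wt$w)
    v_polar <- sum(f * wt$w * solid_angle_factor(wt$x, wt$y))
    conv <- NA_real_
    if (check_convergence) {
      wt2 <- domain_weights(domain, resolution / 2)
      f2 <- predict(interp, cbind(wt2$x, wt2$y))
      v2 <- sum(f2 * wt2$w)
      conv <- abs(v_cart - v2) / max(abs(v2), 1e-12)
    }
    ms <- mean_sensitivity(e)
    bc <- if (!is.null(e$fixation) && nrow(e$fixation) >= 3)
      bcea(e$fixation) else NULL
    data.frame(patient_id = e$patient_id, eye = e$eye,
               ms_db = ms, ms_dbdeg2 = ms_to_area_units(ms, area),
               vtot_cart_dbdeg2 = v_cart,
               vtot_polar_dbsr = v_polar,
               vtot_polar_dbdeg2 = sr_to_deg2(v_polar),
               bcea95_deg2 = if (is.null(bc)) NA_real_ else bc$bcea,
               log10_bcea95 = if (is.null(bc)) NA_real_ else bc$log10_bcea,
               quadrature_convergence = conv)
  })
  out <- do.call(rbind, rows)
  if (!check_convergence) out$quadrature_convergence <- NULL
  if (!is.null(covariates))
    out <- merge(out, covariates, by = c("patient_id", "eye"),
                 all.x = TRUE, sort = FALSE)
  out[order(out$patient_id, out$eye), , drop = FALSE]
}

write_provenance <- function(out_dir, stage, config) {
  rec <- list(stage = stage,
              package = "hovmp",
              version = as.character(utils::packageVersion("hovmp")),
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
              config = config)
  jsonlite::write_json(rec, file.path(out_dir, paste0(stage, "_provenance.json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
}

#' Pipeline stage: simulate a cohort to disk
#'
#' Writes `exams.csv`, `fixation.csv`, `covariates.csv`, and `truth.json`
#' plus a provenance record into `out_dir`.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed RNG seed.
#' @param n_patients Cohort size.
#' @param config Optional full [sim_config()] (overrides `seed`/`n_patients`).
#' @return Invisibly, the simulated cohort list.
#' @export
run_simulate <- function(out_dir, seed = 1, n_patients = 189, config = NULL) {
  if (is.null(config)) config <- sim_config(n_patients = n_patients, seed = seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- simulate_cohort(config)
  write_exam_table(cohort$exams, file.path(out_dir, "exams.csv"))
  fix <- do.call(rbind, lapply(cohort$exams, function(e)
    data.frame(patient_id = e$patient_id, eye = e$eye,
               fx_deg = e$fixation[, 1], fy_deg = e$fixation[, 2])))
  utils::write.csv(fix, file.path(out_dir, "fixation.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(cohort$covariates, file.path(out_dir, "covariates.csv"),
                   row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(eyes = cohort$truth$eyes, scotomas = cohort$truth$scotomas),
    file.path(out_dir, "truth.json"),
    dataframe = "columns", digits = NA)
  write_provenance(out_dir, "simulate",
                   config[setdiff(names(config), "")])
  invisible(cohort)
}

#' Pipeline stage: exams to per-eye metrics table
#'
#' @param exam_csv Exam table path.
#' @param out_dir Output directory.
#' @param fixation_csv,covariate_csv Optional companion tables.
#' @param lambda,resolution Passed to [compute_metrics()].
#' @return Invisibly, the metrics data.frame (also written to
#'   `metrics.csv`).
#' @export
run_compute <- function(exam_csv, out_dir, fixation_csv = NULL,
                        covariate_csv = NULL, lambda = 0, resolution = 0.05) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  exams <- read_exam_table(exam_csv, fixation_path = fixation_csv)
  covs <- if (!is.null(covariate_csv)) read_covariate_table(covariate_csv)
  metrics <- compute_metrics(exams, covariates = covs, lambda = lambda,
                             resolution = resolution)
  write_metrics_table(metrics, file.path(out_dir, "metrics.csv"))
  write_provenance(out_dir, "compute",
                   list(exam_csv = exam_csv, lambda = lambda,
                        resolution = resolution))
  invisible(metrics)
}

#' Pipeline stage: method comparison between two metric columns
#'
#' Harmonizes units where the column names imply a known conversion
#' (dB sr columns are converted to dB deg^2 before differencing), then runs
#' [bland_altman()] and the normality-gated [paired_comparison()], writes
#' `agreement.json` and a Bland-Altman plot.
#'
#' @param metrics_csv Metrics table path (from [run_compute()]).
#' @param col_a,col_b Metric column names to compare.
#' @param out_dir Output directory.
#' @param plot Write `bland_altman.png` (default TRUE).
#' @return Invisibly, a list with the agreement and paired-test results.
#' @export
run_compare <- function(metrics_csv, col_a, col_b, out_dir, plot = TRUE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tab <- read_metrics_table(metrics_csv)
  for (cl in c(col_a, col_b))
    if (!cl %in% names(tab))
      stop(sprintf("column %s not in %s", cl, metrics_csv), call. = FALSE)
  to_common <- function(x, nm) if (grepl("dbsr$", nm)) sr_to_deg2(x) else x
  a <- to_common(tab[[col_a]], col_a)
  b <- to_common(tab[[col_b]], col_b)
  ba <- bland_altman(a, b, name_a = col_a, name_b = col_b)
  pc <- paired_comparison(a, b)
  jsonlite::write_json(
    list(agreement = ba[c("metric_a", "metric_b", "bias", "sd_diff",
                          "loa_low", "loa_high", "n")],
         paired_test = pc),
    file.path(out_dir, "agreement.json"), auto_unbox = TRUE, digits = NA)
  if (plot) {
    p <- plot_bland_altman(ba)
    ggplot2::ggsave(file.path(out_dir, "bland_altman.png"), p,
                    width = 6, height = 4, dpi = 150)
  }
  write_provenance(out_dir, "compare",
                   list(metrics_csv = metrics_csv, col_a = col_a,
                        col_b = col_b))
  invisible(list(agreement = ba, paired_test = pc))
}

#' Pipeline stage: association analysis
#'
#' Univariable mixed models for each candidate covariate, a multivariable
#' model after backward selection (validated by forward BIC selection), and
#' the variable-importance table. Coefficient tables are written to
#' `univariable.csv` / `multivariable.csv`.
#'
#' @param metrics_csv Metrics table path with covariates merged.
#' @param outcome Outcome column (e.g. `"ms_db"` or `"vtot_cart_dbdeg2"`).
#' @param out_dir Output directory.
#' @param candidates Candidate covariates (default the six standard ones).
#' @param plot Write an importance plot for the full multivariable model.
#' @return Invisibly, list with `univariable` (list of fits), `backward`,
#'   `forward`, `final` fit, `importance`.
#' @export
run_associate <- function(metrics_csv, outcome, out_dir,
                          candidates = c("bcva_logmar", "llva_logmar",
                                         "log10_bcea95", "lens_status",
                                         "smoking", "sex"),
                          plot = TRUE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tab <- read_metrics_table(metrics_csv)
  uni <- lapply(candidates, function(v) fit_lmm(tab, outcome, v))
  names(uni) <- candidates
  uni_tab <- do.call(rbind, lapply(candidates, function(v) {
    f <- uni[[v]]
    cbind(covariate = v, f$coefficients,
          r2_marginal = f$r2_marginal, r2_conditional = f$r2_conditional)
  }))
  utils::write.csv(uni_tab, file.path(out_dir, "univariable.csv"),
                   row.names = FALSE)
  bw <- backward_select(tab, outcome, candidates)
  fw <- forward_select_bic(tab, outcome, candidates, backward = bw)
  final <- fit_lmm(tab, outcome, bw$fixed)
  utils::write.csv(
    cbind(final$coefficients, r2_marginal = final$r2_marginal,
          r2_conditional = final$r2_conditional),
    file.path(out_dir, "multivariable.csv"), row.names = FALSE)
  imp <- variable_importance(final)
  if (plot && nrow(imp) > 0) {
    ggplot2::ggsave(file.path(out_dir, "importance.png"),
                    plot_importance(final), width = 6, height = 4, dpi = 150)
  }
  write_provenance(out_dir, "associate",
                   list(metrics_csv = metrics_csv, outcome = outcome,
                        selected = bw$fixed,
                        forward_agrees = isTRUE(fw$agrees_with_backward)))
  invisible(list(univariable = uni, backward = bw, forward = fw,
                 final = final, importance = imp))
}
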
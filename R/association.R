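#' Fit a nested linear mixed-effects association model
#'
#' Regresses a retinal-sensitivity metric on per-eye covariates with eyes
#' nested in patients as the random-effects structure, estimated by REML
#' through \pkg{lme4}/\pkg{lmerTest}. t-statistics use Satterthwaite
#' denominator degrees of freedom; 95% confidence intervals are
#' `estimate +/- t(0.975, df) * SE`.
#'
#' With one exam per eye (the usual cross-sectional design) the
#' eye-within-patient variance component is not separable from the residual;
#' the model then carries a random intercept per patient and the eye-level
#' variance is reported merged into the residual (`eye_merged = TRUE`).
#' When eyes have replicate rows, an explicit eye-within-patient intercept
#' `(1 | patient:eye)` is added.
#'
#' Multivariable fits whose fixed-effect design is numerically collinear
#' (condition number above `kappa_max`) are refused with an actionable
#' message; highly correlated acuity measures (BCVA/LLVA) are the typical
#' trigger.
#'
#' @param table Cohort data.frame with columns `patient_id`, `eye`, the
#'   outcome, and the covariates.
#' @param outcome Name of the dependent metric column.
#' @param fixed Character vector of fixed-effect covariate names (may be
#'   empty for the intercept-only null model).
#' @param reml Fit by REML (default) or ML (needed for BIC comparisons).
#' @param kappa_max Condition-number limit for the fixed design.
#' @return Object of class `hov_lmm`: `coefficients` (data.frame with
#'   estimate, SE, df, t, p, CI), `varcomp` (patient/eye/residual variances,
#'   `eye_merged`), `var_fixed`, `r2_marginal`, `r2_conditional`, `bic`,
#'   `n_obs`, `n_patients`, `outcome`, `fixed`, and the underlying `fit`.
#' @export
fit_lmm <- function(table, outcome, fixed = character(), reml = TRUE,
                    kappa_max = 1e6) {
  stopifnot(is.data.frame(table))
  need <- c("patient_id", "eye", outcome, fixed)
  miss <- setdiff(need, names(table))
  if (length(miss))
    stop(sprintf("missing columns: %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  dat <- table[stats::complete.cases(table[, need, drop = FALSE]), , drop = FALSE]
  dat$patient_id <- factor(dat$patient_id)
  dat$.eye_uid <- interaction(dat$patient_id, dat$eye, drop = TRUE)

  if (length(fixed) >= 2L) {
    # condition number of the full fixed design (intercept included, so
    # affine dependences like BCVA = a + b*LLVA register as collinear)
    X <- stats::model.matrix(stats::reformulate(fixed), data = dat)
    if (ncol(X) >= 2L) {
      Xs <- sweep(X, 2, sqrt(colSums(X^2)), "/")
      d <- svd(Xs, nu = 0, nv = 0)$d
      cond <- if (min(d) <= 0) Inf else max(d) / min(d)
      if (cond > kappa_max)
        stop(sprintf(paste0("fixed-effect design is collinear (condition ",
                            "number %.3g > %.0g); drop one of the correlated ",
                            "covariates (e.g. keep only one of BCVA/LLVA)"),
                     cond, kappa_max), call. = FALSE)
    }
  }

  replicated <- anyDuplicated(dat$.eye_uid) > 0L
  rand <- if (replicated) "(1 | patient_id) + (1 | .eye_uid)"
          else "(1 | patient_id)"
  ctrl <- lme4::lmerControl()
  if (nlevels(dat$patient_id) == nrow(dat)) {
    warning(paste("all patients contribute a single observation;",
                  "patient variance is not separable from the residual"),
            call. = FALSE)
    ctrl <- lme4::lmerControl(check.nobs.vs.nlev = "ignore",
                              check.nobs.vs.nRE = "ignore")
  }
  rhs <- paste(c(if (length(fixed)) fixed else "1", rand), collapse = " + ")
  form <- stats::as.formula(paste(outcome, "~", rhs))
  fit <- lmerTest::lmer(form, data = dat, REML = reml, control = ctrl)

  cf <- as.data.frame(stats::coef(summary(fit)))
  names(cf) <- c("estimate", "se", "df", "t", "p")
  tq <- stats::qt(0.975, pmax(cf$df, 1))
  cf$ci_low <- cf$estimate - tq * cf$se
  cf$ci_high <- cf$estimate + tq * cf$se
  cf <- cbind(term = rownames(cf), cf)
  rownames(cf) <- NULL

  vc <- as.data.frame(lme4::VarCorr(fit))
  var_of <- function(grp) {
    i <- which(vc$grp == grp)
    if (length(i)) vc$vcov[i] else 0
  }
  varcomp <- list(patient = var_of("patient_id"),
                  eye = if (replicated) var_of(".eye_uid") else 0,
                  residual = var_of("Residual"),
                  eye_merged = !replicated)
  var_fixed <- if (length(fixed) == 0L) 0 else {
    eta <- stats::model.matrix(fit) %*% lme4::fixef(fit)
    stats::var(as.numeric(eta))
  }
  r2 <- nakagawa_r2(list(var_fixed = var_fixed, var_patient = varcomp$patient,
                         var_eye = varcomp$eye,
                         var_resid = varcomp$residual))
  structure(list(coefficients = cf, varcomp = varcomp, var_fixed = var_fixed,
                 r2_marginal = r2[["r2_marginal"]],
                 r2_conditional = r2[["r2_conditional"]],
                 bic = stats::BIC(fit), n_obs = nrow(dat),
                 n_patients = nlevels(dat$patient_id), outcome = outcome,
                 fixed = fixed, reml = reml, fit = fit),
            class = "hov_lmm")
}

#' @export
print.hov_lmm <- function(x, ...) {
  cat(sprintf("<hov_lmm> %s ~ %s, eyes nested in patients (n = %d eyes, %d patients)\n",
              x$outcome,
              if (length(x$fixed)) paste(x$fixed, collapse = " + ") else "1",
              x$n_obs, x$n_patients))
  print(x$coefficients, digits = 4)
  cat(sprintf("variance: patient %.4g, eye %s, residual %.4g\n",
              x$varcomp$patient,
              if (x$varcomp$eye_merged) "(merged into residual)"
              else sprintf("%.4g", x$varcomp$eye),
              x$varcomp$residual))
  cat(sprintf("R2 marginal %.4g, conditional %.4g; BIC %.4g\n",
              x$r2_marginal, x$r2_conditional, x$bic))
  invisible(x)
}

#' Marginal and conditional R-squared of a mixed model
#'
#' Nakagawa-style variance decomposition: the marginal R^2 is the variance
#' of the fixed-effect linear predictor over the total (fixed + patient +
#' eye + residual) variance; the conditional R^2 adds the random-effect
#' variances to the numerator.
#'
#' @param fit An [fit_lmm()] result, or a named list with components
#'   `var_fixed`, `var_patient`, `var_eye`, `var_resid`.
#' @return Named numeric vector `c(r2_marginal, r2_conditional)`.
#' @export
nakagawa_r2 <- function(fit) {
  if (inherits(fit, "hov_lmm")) {
    v <- list(var_fixed = fit$var_fixed, var_patient = fit$varcomp$patient,
              var_eye = fit$varcomp$eye, var_resid = fit$varcomp$residual)
  } else {
    v <- fit
    stopifnot(all(c("var_fixed", "var_patient", "var_eye", "var_resid")
                  %in% names(v)))
  }
  tot <- v$var_fixed + v$var_patient + v$var_eye + v$var_resid
  if (tot <= 0) stop("zero total variance: R^2 undefined", call. = FALSE)
  c(r2_marginal = v$var_fixed / tot,
    r2_conditional = (v$var_fixed + v$var_patient + v$var_eye) / tot)
}

#' Backward fixed-effect selection by F-tests
#'
#' Starting from the full candidate set, iteratively refits the mixed model
#' and drops the fixed term with the largest Satterthwaite F-test p-value
#' above `alpha`, until every remaining term is significant (possibly
#' leaving the intercept-only model). Ties are broken by covariate name
#' order.
#'
#' @param table Cohort data.frame.
#' @param outcome Dependent metric column name.
#' @param candidates Character vector of candidate covariates.
#' @param alpha Retention threshold (default 0.05).
#' @return List with `outcome`, `fixed` (selected covariates), and
#'   `history` (data.frame of dropped terms and their p-values).
#' @export
backward_select <- function(table, outcome, candidates, alpha = 0.05) {
  current <- sort(candidates)
  history <- list()
  while (length(current) > 0L) {
    fit <- fit_lmm(table, outcome, current)
    av <- stats::anova(fit$fit)   # lmerTest: Satterthwaite F per fixed term
    p <- av[["Pr(>F)"]]
    names(p) <- rownames(av)
    p <- p[current]
    worst <- names(p)[order(-p, names(p))][1]
    if (is.na(p[worst]) || p[worst] <= alpha) break
    history[[length(history) + 1L]] <-
      data.frame(dropped = worst, p = unname(p[worst]))
    current <- setdiff(current, worst)
  }
  list(outcome = outcome, fixed = current,
       history = if (length(history)) do.call(rbind, history)
                 else data.frame(dropped = character(), p = numeric()))
}

#' Forward fixed-effect selection by BIC
#'
#' Greedy forward selection on maximum-likelihood fits: at each step the
#' candidate whose addition lowers the model BIC the most is added; the
#' search stops when no addition lowers BIC. Candidates whose addition
#' makes the fixed design collinear are skipped. Used to validate
#' [backward_select()]; the result reports whether the two agree.
#'
#' @inheritParams backward_select
#' @param backward Optional result of [backward_select()] to compare with.
#' @return List with `outcome`, `fixed`, `history` (BIC trace), and, when
#'   `backward` is given, `agrees_with_backward`.
#' @export
forward_select_bic <- function(table, outcome, candidates, backward = NULL) {
  current <- character()
  bic <- fit_lmm(table, outcome, current, reml = FALSE)$bic
  remaining <- sort(candidates)
  history <- list(data.frame(added = "(intercept)", bic = bic))
  repeat {
    if (length(remaining) == 0L) break
    trial <- vapply(remaining, function(cand) {
      tryCatch(fit_lmm(table, outcome, c(current, cand), reml = FALSE)$bic,
               error = function(e) Inf)
    }, numeric(1))
    best <- names(trial)[order(trial, names(trial))][1]
    if (trial[best] >= bic) break
    bic <- trial[best]
    current <- c(current, best)
    remaining <- setdiff(remaining, best)
    history[[length(history) + 1L]] <- data.frame(added = best, bic = bic)
  }
  out <- list(outcome = outcome, fixed = sort(current),
              history = do.call(rbind, history))
  if (!is.null(backward))
    out$agrees_with_backward <- setequal(out$fixed, backward$fixed)
  out
}

#' Fixed-effect variable importance
#'
#' Orders the fixed-effect terms of a multivariable fit by the magnitude of
#' their t-statistics (signs preserved), the presentation used for
#' variable-importance plots.
#'
#' @param fit An [fit_lmm()] result.
#' @return data.frame with `term`, `t`, `p`, sorted by `|t|` descending.
#' @export
variable_importance <- function(fit) {
  stopifnot(inherits(fit, "hov_lmm"))
  cf <- fit$coefficients
  cf <- cf[cf$term != "(Intercept)", c("term", "t", "p"), drop = FALSE]
  cf <- cf[order(-abs(cf$t)), , drop = FALSE]
  rownames(cf) <- NULL
  cf
}
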
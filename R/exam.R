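#' Construct a microperimetry exam
#'
#' One eye's recording: per-point sensitivity thresholds on a test grid,
#' optionally with fixation samples. Thresholds are in decibels on the MAIA
#' 0-36 dB dynamic range; the device's "not seen" code (-1) is stored as
#' 0 dB with a `not_seen` flag so sensitivity analyses can exclude those
#' points.
#'
#' @param patient_id Patient identifier (character).
#' @param eye `"right"` or `"left"`.
#' @param points Two-column matrix/data.frame of test-point positions
#'   (degrees, visual-field cartesian, fixation at the origin).
#' @param thresholds Numeric vector of sensitivities in dB, one per point;
#'   value -1 means "not seen".
#' @param fixation Optional two-column matrix/data.frame of fixation samples
#'   (degrees).
#' @param grid Grid the exam is tested against (default [pinnacle_grid()]).
#' @param visit,device Optional metadata labels.
#' @return Object of class `mp_exam`.
#' @export
mp_exam <- function(patient_id, eye, points, thresholds, fixation = NULL,
                    grid = pinnacle_grid(), visit = NA_character_,
                    device = NA_character_) {
  eye <- match.arg(eye, c("right", "left"))
  pts <- as_point_matrix(points)
  thresholds <- as.numeric(thresholds)
  if (nrow(pts) != length(thresholds))
    stop("one threshold per point required", call. = FALSE)
  if (any(!is.finite(thresholds)))
    stop("thresholds must be finite", call. = FALSE)
  if (any(thresholds < -1 | thresholds > 36))
    stop(sprintf("threshold outside [-1, 36] dB for patient %s (%s eye)",
                 patient_id, eye), call. = FALSE)
  not_seen <- thresholds == -1
  thresholds[not_seen] <- 0
  if (!is.null(fixation)) fixation <- as_point_matrix(fixation)
  structure(list(patient_id = as.character(patient_id), eye = eye,
                 points = pts, thresholds = thresholds, not_seen = not_seen,
                 fixation = fixation, grid = grid, visit = visit,
                 device = device),
            class = "mp_exam")
}

#' @export
print.mp_exam <- function(x, ...) {
  cat(sprintf("<mp_exam> patient %s, %s eye: %d points, MS %.2f dB%s\n",
              x$patient_id, x$eye, length(x$thresholds),
              mean(x$thresholds),
              if (is.null(x$fixation)) "" else
                sprintf(", %d fixation samples", nrow(x$fixation))))
  invisible(x)
}

#' Validate an exam against its grid
#'
#' Returns machine-readable data-quality issues rather than raising errors:
#' off-grid points (no canonical grid point within the matching tolerance),
#' out-of-range thresholds, wrong point count, duplicate grid points, and
#' missing fixation data. An empty result means the exam is analyzable.
#'
#' @param exam An [mp_exam()].
#' @param tol Grid-matching tolerance in degrees (default 0.25, well below
#'   the 2-degree inter-point spacing).
#' @return data.frame with columns `code`, `detail`; zero rows if clean.
#' @export
validate_exam <- function(exam, tol = 0.25) {
  stopifnot(inherits(exam, "mp_exam"))
  issues <- list()
  add <- function(code, detail)
    issues[[length(issues) + 1L]] <<- data.frame(code = code, detail = detail)
  n_grid <- nrow(exam$grid$points)
  if (nrow(exam$points) != n_grid)
    add("point_count", sprintf("expected %d points, found %d",
                               n_grid, nrow(exam$points)))
  idx <- match_grid_points(exam$points, exam$grid, tol = tol)
  for (k in which(is.na(idx)))
    add("off_grid", sprintf("point (%g, %g) matches no grid location",
                            exam$points[k, 1], exam$points[k, 2]))
  dup <- idx[!is.na(idx)]
  for (j in unique(dup[duplicated(dup)]))
    add("duplicate_point", sprintf("grid location (%g, %g) tested more than once",
                                   exam$grid$points$x[j], exam$grid$points$y[j]))
  bad <- which(exam$thresholds < 0 | exam$thresholds > 36)
  for (k in bad)
    add("threshold_range", sprintf("threshold %g dB outside [0, 36]",
                                   exam$thresholds[k]))
  if (is.null(exam$fixation))
    add("no_fixation", "no fixation samples; BCEA95 unavailable")
  if (length(issues) == 0L)
    data.frame(code = character(), detail = character())
  else
    do.call(rbind, issues)
}

#' Read microperimetry exams from a CSV table
#'
#' Expects one row per tested point with header columns `patient_id`, `eye`,
#' `x_deg`, `y_deg`, `threshold_db` and optional `visit`, `device`. An
#' optional companion fixation table has columns `patient_id`, `eye`,
#' `fx_deg`, `fy_deg`. Files are comma-separated UTF-8 with "." decimal.
#' Rows are grouped into one exam per (patient, eye); each exam is checked
#' for completeness against the grid and duplicate points are rejected.
#' Device value -1 ("not seen") is mapped to 0 dB with a flag.
#'
#' @param path Exam CSV path.
#' @param fixation_path Optional fixation CSV path.
#' @param grid Expected grid (default [pinnacle_grid()]).
#' @param tol Grid matching tolerance in degrees.
#' @return List of [mp_exam()] objects.
#' @export
read_exam_table <- function(path, fixation_path = NULL,
                            grid = pinnacle_grid(), tol = 0.25) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "eye", "x_deg", "y_deg", "threshold_db")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop(sprintf("%s: missing required columns: %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  if (any(tab$threshold_db < -1 | tab$threshold_db > 36))
    stop(sprintf("%s: threshold outside [-1, 36] dB", path), call. = FALSE)

  fix <- NULL
  if (!is.null(fixation_path)) {
    fix <- utils::read.csv(fixation_path, stringsAsFactors = FALSE)
    fneed <- c("patient_id", "eye", "fx_deg", "fy_deg")
    fmiss <- setdiff(fneed, names(fix))
    if (length(fmiss))
      stop(sprintf("%s: missing required columns: %s", fixation_path,
                   paste(fmiss, collapse = ", ")), call. = FALSE)
  }

  key <- interaction(tab$patient_id, tab$eye, drop = TRUE)
  n_grid <- nrow(grid$points)
  exams <- lapply(split(tab, key), function(d) {
    who <- sprintf("patient %s (%s eye)", d$patient_id[1], d$eye[1])
    if (nrow(d) != n_grid)
      stop(sprintf("incomplete exam for %s: %d of %d points", who,
                   nrow(d), n_grid), call. = FALSE)
    idx <- match_grid_points(cbind(d$x_deg, d$y_deg), grid, tol = tol)
    if (anyNA(idx))
      stop(sprintf("off-grid point for %s", who), call. = FALSE)
    if (anyDuplicated(idx))
      stop(sprintf("duplicate grid point for %s", who), call. = FALSE)
    fx <- NULL
    if (!is.null(fix)) {
      f <- fix[fix$patient_id == d$patient_id[1] & fix$eye == d$eye[1], ]
      if (nrow(f) > 0) fx <- cbind(f$fx_deg, f$fy_deg)
    }
    mp_exam(patient_id = d$patient_id[1], eye = d$eye[1],
            points = cbind(d$x_deg, d$y_deg), thresholds = d$threshold_db,
            fixation = fx, grid = grid,
            visit = if ("visit" %in% names(d)) d$visit[1] else NA_character_,
            device = if ("device" %in% names(d)) d$device[1] else NA_character_)
  })
  unname(exams)
}

#' Write exams back to the exam CSV dialect
#'
#' Inverse of [read_exam_table()]; flagged not-seen points are written with
#' the device code -1.
#'
#' @param exams List of [mp_exam()] objects.
#' @param path Destination CSV path.
#' @export
write_exam_table <- function(exams, path) {
  rows <- lapply(exams, function(e) {
    thr <- e$thresholds
    thr[e$not_seen] <- -1
    data.frame(patient_id = e$patient_id, eye = e$eye,
               x_deg = e$points[, 1], y_deg = e$points[, 2],
               threshold_db = thr, visit = e$visit, device = e$device)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read the per-eye covariate table
#'
#' Columns: `patient_id`, `eye`, `bcva_logmar`, `llva_logmar`, `lens_status`
#' (phakic/pseudophakic), `smoking` (Never smoked / Ex-smoker / Current
#' smoker), `sex` (female/male). Categorical columns become factors with
#' reference levels phakic, Never smoked, female (treatment coding).
#'
#' @param path Covariate CSV path.
#' @return data.frame.
#' @export
read_covariate_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "eye", "bcva_logmar", "llva_logmar",
            "lens_status", "smoking", "sex")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop(sprintf("%s: missing required columns: %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  as_covariate_factors(tab)
}

# Treatment coding with clinical reference levels.
as_covariate_factors <- function(tab) {
  if ("lens_status" %in% names(tab))
    tab$lens_status <- factor(tab$lens_status,
                              levels = c("phakic", "pseudophakic"))
  if ("smoking" %in% names(tab))
    tab$smoking <- factor(tab$smoking,
                          levels = c("Never smoked", "Ex-smoker",
                                     "Current smoker"))
  if ("sex" %in% names(tab))
    tab$sex <- factor(tab$sex, levels = c("female", "male"))
  tab
}

#' Write a per-eye metrics table
#'
#' One row per eye; numeric columns serialized at 12 significant digits so
#' a write/read round trip preserves values.
#'
#' @param cohort data.frame keyed by (`patient_id`, `eye`).
#' @param path Destination CSV path.
#' @export
write_metrics_table <- function(cohort, path) {
  stopifnot(is.data.frame(cohort))
  if (nrow(cohort) > 0 &&
      anyDuplicated(cohort[, c("patient_id", "eye")]))
    stop("each eye may appear at most once in a cohort table", call. = FALSE)
  out <- cohort
  for (j in seq_along(out))
    if (is.numeric(out[[j]])) out[[j]] <- signif(out[[j]], 12)
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    stop(sprintf("failed to write metrics table to %s: %s",
                 path, conditionMessage(ok)), call. = FALSE)
  invisible(path)
}

#' Read a per-eye metrics table written by [write_metrics_table()]
#' @param path Metrics CSV path.
#' @return data.frame.
#' @export
read_metrics_table <- function(path) {
  as_covariate_factors(utils::read.csv(path, stringsAsFactors = FALSE))
}
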
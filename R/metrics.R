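#' Mean sensitivity of an exam
#'
#' The classical microperimetry summary: the arithmetic mean of the
#' per-point thresholds, in dB.
#'
#' @param exam An [mp_exam()].
#' @return Mean sensitivity in dB.
#' @export
mean_sensitivity <- function(exam) {
  stopifnot(inherits(exam, "mp_exam"))
  n_grid <- nrow(exam$grid$points)
  if (length(exam$thresholds) != n_grid || any(!is.finite(exam$thresholds)))
    stop(sprintf("incomplete exam: expected %d finite thresholds", n_grid),
         call. = FALSE)
  mean(exam$thresholds)
}

#' Convert mean sensitivity to planar volume units
#'
#' Multiplies a mean sensitivity (dB) by the tested grid area (deg^2),
#' putting MS on the same dB deg^2 scale as a cartesian VTOT. For a
#' constant sensitivity surface the two are identical.
#'
#' @param ms Mean sensitivity in dB.
#' @param area Grid area in deg^2 (the 24-point grid's hull covers 68 deg^2).
#' @return Value in dB deg^2.
#' @export
ms_to_area_units <- function(ms, area = 68) {
  if (!is.numeric(area) || any(area <= 0))
    stop("area must be positive", call. = FALSE)
  ms * area
}

#' Convert between steradian and square-degree volume units
#'
#' `1 sr = (180/pi)^2` (about 3282.8) square degrees; the conversions are
#' exact multiplicative inverses of each other.
#'
#' @param v Value in dB sr (for `sr_to_deg2`) or dB deg^2 (for
#'   `deg2_to_sr`).
#' @return Converted value.
#' @export
sr_to_deg2 <- function(v) v * DEG2_PER_SR

#' @rdname sr_to_deg2
#' @export
deg2_to_sr <- function(v) v / DEG2_PER_SR

#' Bivariate contour ellipse area of fixation samples
#'
#' Area of the probability ellipse containing a fraction `coverage` of a
#' bivariate normal fitted to the fixation scatter:
#'
#' \deqn{BCEA_P = \pi \, \chi^2_2(P) \, \sigma_x \sigma_y \sqrt{1 - \rho^2}}
#'
#' with sample (n-1) standard deviations and sample correlation, and
#' `chi^2_2(P) = -2 log(1 - P)` (5.9915 at 95% coverage). This is the
#' standard probability-ellipse definition used in the fixation-stability
#' literature; note that legacy device firmware sometimes uses a fixed
#' multiplier instead of the chi-square quantile, so cross-device
#' comparisons should confirm the convention.
#'
#' @param fixation_samples Two-column matrix/data.frame of fixation
#'   positions in degrees.
#' @param coverage Ellipse coverage probability in (0, 1); default 0.95.
#' @return List with `bcea` (deg^2), `log10_bcea`, `sigma_x`, `sigma_y`,
#'   `rho`, `coverage`, `n`.
#' @export
bcea <- function(fixation_samples, coverage = 0.95) {
  m <- as_point_matrix(fixation_samples)
  if (nrow(m) < 3L)
    stop("need at least 3 fixation samples", call. = FALSE)
  if (!is.numeric(coverage) || coverage <= 0 || coverage >= 1)
    stop("coverage must be in (0, 1)", call. = FALSE)
  sx <- stats::sd(m[, 1]); sy <- stats::sd(m[, 2])
  if (sx < 1e-12 || sy < 1e-12)
    stop("degenerate fixation scatter: zero variance along an axis",
         call. = FALSE)
  rho <- stats::cor(m[, 1], m[, 2])
  if (1 - rho^2 < 1e-12)
    stop("degenerate fixation scatter: samples are perfectly correlated",
         call. = FALSE)
  k <- -2 * log(1 - coverage)   # chi-square quantile with 2 df
  area <- pi * k * sx * sy * sqrt(1 - rho^2)
  list(bcea = area, log10_bcea = log10(area), sigma_x = sx, sigma_y = sy,
       rho = rho, coverage = coverage, n = nrow(m))
}
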
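#' Configuration for the synthetic iAMD cohort generator
#'
#' Defaults emulate the statistical structure of a large intermediate-AMD
#' microperimetry cohort: 189 patients contributing one or two eyes
#' (`p_two_eyes` 0.31 gives about 247 eyes), a gently dome-shaped true
#' sensitivity surface (base 26 dB minus an eccentricity falloff of 0.06
#' dB/deg^2) with nested patient/eye/test noise (2 / 1 / 1.5 dB), sparse
#' focal Gaussian scotomata (Poisson rate 0.5 per eye, depth 5-20 dB,
#' radius 0.8-2 deg), low-luminance acuity linearly linked to mean true
#' sensitivity with a negative sensitivity coefficient, BCVA correlated with
#' LLVA at 0.8, categorical covariates at published iAMD cohort frequencies
#' (35.2% pseudophakic; smoking 42.1/49.8/8.1% never/ex/current; 64% female),
#' and bivariate-normal fixation scatter.
#'
#' @param n_patients Number of patients.
#' @param p_two_eyes Probability a patient contributes both eyes.
#' @param base_sensitivity Foveal plateau of the true surface, dB.
#' @param ecc_slope Quadratic eccentricity falloff, dB per deg^2.
#' @param sigma_patient,sigma_eye,sigma_test Nested SDs, dB.
#' @param scotoma List: `rate` (Poisson mean per eye), `depth_range` (dB),
#'   `radius_range` (deg), `center_radius` (centers uniform in this disc).
#' @param llva_link List `gamma0`, `gamma1`, `sigma`: LLVA logMAR =
#'   `gamma0 - gamma1 * (mean true sensitivity) + N(0, sigma^2)`.
#' @param bcva List `mean`, `sd`, `corr_llva`.
#' @param freq List of categorical frequencies: `pseudophakic`, `smoking`
#'   (named never/ex/current), `female`.
#' @param fixation List `sigma_range` (deg), `rho_range`, `n_samples`.
#' @param seed RNG seed; the seed fully determines the cohort (R's default
#'   Mersenne-Twister generator).
#' @return Validated config list of class `sim_config`.
#' @export
sim_config <- function(n_patients = 189,
                       p_two_eyes = 0.31,
                       base_sensitivity = 26,
                       ecc_slope = 0.06,
                       sigma_patient = 2,
                       sigma_eye = 1,
                       sigma_test = 1.5,
                       scotoma = list(rate = 0.5, depth_range = c(5, 20),
                                      radius_range = c(0.8, 2),
                                      center_radius = 5),
                       llva_link = list(gamma0 = 0.95, gamma1 = 0.025,
                                        sigma = 0.15),
                       bcva = list(mean = 0.02, sd = 0.12, corr_llva = 0.8),
                       freq = list(pseudophakic = 0.352,
                                   smoking = c(never = 0.421, ex = 0.498,
                                               current = 0.081),
                                   female = 0.64),
                       fixation = list(sigma_range = c(0.02, 0.17),
                                       rho_range = c(-0.5, 0.5),
                                       n_samples = 300),
                       seed = 1) {
  stopifnot(n_patients >= 1,
            p_two_eyes >= 0, p_two_eyes <= 1,
            sigma_patient >= 0, sigma_eye >= 0, sigma_test >= 0,
            scotoma$rate >= 0, all(scotoma$depth_range >= 0),
            all(scotoma$radius_range > 0),
            llva_link$sigma >= 0, bcva$sd >= 0,
            abs(bcva$corr_llva) <= 1,
            freq$pseudophakic >= 0, freq$pseudophakic <= 1,
            abs(sum(freq$smoking) - 1) < 1e-9,
            freq$female >= 0, freq$female <= 1,
            all(fixation$sigma_range > 0), fixation$n_samples >= 3)
  structure(as.list(environment()), class = "sim_config")
}

# True hill-of-vision surface for one eye: constant plateau minus quadratic
# eccentricity falloff minus Gaussian scotomata.
true_surface <- function(const, ecc_slope, scot) {
  force(const); force(ecc_slope); force(scot)
  function(x, y) {
    s <- const - ecc_slope * (x^2 + y^2)
    if (!is.null(scot) && nrow(scot) > 0) {
      for (k in seq_len(nrow(scot))) {
        d2 <- (x - scot$cx[k])^2 + (y - scot$cy[k])^2
        s <- s - scot$depth[k] * exp(-d2 / (2 * scot$radius[k]^2))
      }
    }
    s
  }
}

#' Simulate a synthetic iAMD microperimetry cohort
#'
#' Draws a full cohort under [sim_config()]: per-patient and per-eye latent
#' sensitivity offsets, true surfaces with focal scotomata, integer MAIA
#' thresholds (Gaussian test-retest noise, rounded, clamped to the 0-36 dB
#' dynamic range, with sub-floor responses encoded as "not seen"),
#' sensitivity-linked LLVA, correlated BCVA, categorical covariates, and
#' per-eye fixation clouds. Alongside the exams, a truth record stores each
#' eye's surface parameters and oracle quantities for recovery testing; the
#' analysis path never reads it.
#'
#' @param config A [sim_config()].
#' @param grid Test grid (default [pinnacle_grid()]).
#' @return List with `exams` (list of [mp_exam()]), `covariates`
#'   (data.frame), and `truth` (list: `eyes` data.frame, `scotomas`
#'   data.frame, `config`).
#' @export
simulate_cohort <- function(config = sim_config(), grid = pinnacle_grid()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  gpts <- as_point_matrix(grid$points)
  exams <- list()
  cov_rows <- list()
  truth_rows <- list()
  scot_rows <- list()

  for (p in seq_len(config$n_patients)) {
    pid <- sprintf("P%04d", p)
    h <- stats::rnorm(1, 0, config$sigma_patient)
    two <- stats::runif(1) < config$p_two_eyes
    first <- sample(c("right", "left"), 1)
    eyes <- if (two) c(first, setdiff(c("right", "left"), first)) else first
    smoking <- sample(c("Never smoked", "Ex-smoker", "Current smoker"), 1,
                      prob = config$freq$smoking[c("never", "ex", "current")])
    sex <- if (stats::runif(1) < config$freq$female) "female" else "male"

    for (eye in eyes) {
      e <- stats::rnorm(1, 0, config$sigma_eye)
      n_scot <- stats::rpois(1, config$scotoma$rate)
      scot <- NULL
      if (n_scot > 0) {
        ang <- stats::runif(n_scot, 0, 2 * pi)
        rad <- config$scotoma$center_radius * sqrt(stats::runif(n_scot))
        scot <- data.frame(
          patient_id = pid, eye = eye,
          depth = stats::runif(n_scot, config$scotoma$depth_range[1],
                               config$scotoma$depth_range[2]),
          radius = stats::runif(n_scot, config$scotoma$radius_range[1],
                                config$scotoma$radius_range[2]),
          cx = rad * cos(ang), cy = rad * sin(ang))
        scot_rows[[length(scot_rows) + 1L]] <- scot
      }
      const <- config$base_sensitivity + h + e
      surf <- true_surface(const, config$ecc_slope, scot)
      s_true <- surf(gpts[, 1], gpts[, 2])
      raw <- s_true + stats::rnorm(nrow(gpts), 0, config$sigma_test)
      thr <- round(raw)
      thr[thr > 36] <- 36
      thr[thr < 0] <- -1          # device "not seen" code
      fx <- {
        sr <- config$fixation$sigma_range
        rr <- config$fixation$rho_range
        simulate_fixation(stats::runif(1, sr[1], sr[2]),
                          stats::runif(1, sr[1], sr[2]),
                          stats::runif(1, rr[1], rr[2]),
                          config$fixation$n_samples)
      }
      exams[[length(exams) + 1L]] <-
        mp_exam(pid, eye, gpts, thr, fixation = fx, grid = grid,
                visit = "baseline", device = "synthetic-MAIA")

      ms_true <- mean(s_true)
      llva <- config$llva_link$gamma0 -
        config$llva_link$gamma1 * ms_true +
        stats::rnorm(1, 0, config$llva_link$sigma)
      lens <- if (stats::runif(1) < config$freq$pseudophakic)
        "pseudophakic" else "phakic"
      cov_rows[[length(cov_rows) + 1L]] <- data.frame(
        patient_id = pid, eye = eye, llva_logmar = llva,
        lens_status = lens, smoking = smoking, sex = sex)
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        patient_id = pid, eye = eye, const = const,
        ecc_slope = config$ecc_slope, n_scotomas = n_scot,
        true_ms = ms_true)
    }
  }

  covariates <- do.call(rbind, cov_rows)
  # BCVA correlated with LLVA at the configured level (empirical
  # standardization so the generated correlation matches the target)
  zl <- as.numeric(scale(covariates$llva_logmar))
  rho <- config$bcva$corr_llva
  covariates$bcva_logmar <- config$bcva$mean + config$bcva$sd *
    (rho * zl + sqrt(1 - rho^2) * stats::rnorm(nrow(covariates)))
  covariates <- as_covariate_factors(
    covariates[, c("patient_id", "eye", "bcva_logmar", "llva_logmar",
                   "lens_status", "smoking", "sex")])
  truth <- list(eyes = do.call(rbind, truth_rows),
                scotomas = if (length(scot_rows)) do.call(rbind, scot_rows)
                           else data.frame(patient_id = character(),
                                           eye = character(),
                                           depth = numeric(),
                                           radius = numeric(),
                                           cx = numeric(), cy = numeric()),
                config = config)
  list(exams = exams, covariates = covariates, truth = truth)
}

#' Oracle volume of a true (generator) surface
#'
#' Integrates the generator's *true* surface — not a thin-plate-spline fit —
#' over a domain by high-resolution planar quadrature (default 0.01 deg
#' raster with exact-overlap boundary weights). Used to quantify the bias
#' of the TPS volume estimate against ground truth; the constant and
#' quadratic terms can additionally be cross-checked against exact polygon
#' moments.
#'
#' @param truth Truth record from [simulate_cohort()].
#' @param patient_id,eye Which eye's surface to integrate.
#' @param domain [integration_domain()]; default convex hull of the
#'   24-point grid.
#' @param resolution Raster resolution in degrees (default 0.01).
#' @return Volume in dB deg^2.
#' @export
oracle_vtot <- function(truth, patient_id, eye, domain = NULL,
                        resolution = 0.01) {
  row <- truth$eyes[truth$eyes$patient_id == patient_id &
                      truth$eyes$eye == eye, , drop = FALSE]
  if (nrow(row) != 1L)
    stop("no unique truth record for that patient/eye", call. = FALSE)
  scot <- truth$scotomas[truth$scotomas$patient_id == patient_id &
                           truth$scotomas$eye == eye, , drop = FALSE]
  surf <- true_surface(row$const, row$ecc_slope, scot)
  if (is.null(domain))
    domain <- integration_domain("convex_hull",
                                 points = pinnacle_grid()$points)
  wt <- domain_weights(domain, resolution)
  sum(surf(wt$x, wt$y) * wt$w)
}

#' Draw bivariate-normal fixation samples
#'
#' @param sigma_x,sigma_y Marginal SDs in degrees (positive).
#' @param rho Correlation, `|rho| < 1`.
#' @param n Number of samples.
#' @param seed Optional seed; if `NULL` the current RNG stream is used.
#' @return n x 2 matrix of fixation positions (degrees).
#' @export
simulate_fixation <- function(sigma_x, sigma_y, rho, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (sigma_x <= 0 || sigma_y <= 0)
    stop("sigma_x and sigma_y must be positive", call. = FALSE)
  if (abs(rho) >= 1)
    stop("|rho| must be < 1", call. = FALSE)
  z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
  cbind(x = sigma_x * z1,
        y = sigma_y * (rho * z1 + sqrt(1 - rho^2) * z2))
}

#' Simulate a cohort table with planted fixed-effect slopes
#'
#' Table-level generator for mixed-model validation: covariates are drawn
#' exogenously and the outcome is built directly as
#' `intercept + X beta + patient effect + eye effect + residual`, so the
#' regression coefficients are *planted*, known quantities (in the full
#' forward model of [simulate_cohort()] the sensitivity-acuity slope is
#' emergent instead). Used for coverage, type-I-error, and
#' variable-selection simulations.
#'
#' @param n_patients Number of patients (default 190).
#' @param p_two_eyes Probability of contributing both eyes (default 0.6).
#' @param beta Named numeric vector of planted slopes on numeric covariate
#'   columns (default `c(llva_logmar = -4.6)`, a realistic
#'   sensitivity-vs-LLVA slope in dB per logMAR).
#' @param intercept Outcome intercept, dB.
#' @param sd_patient,sd_eye,sd_resid Nested SDs, dB.
#' @param bcva_llva_corr Correlation between the two acuity covariates.
#' @param outcome Name of the outcome column (default `"ms_db"`).
#' @param seed RNG seed.
#' @return List with `table` (data.frame) and `truth` (planted parameters).
#' @export
simulate_lmm_table <- function(n_patients = 190, p_two_eyes = 0.6,
                               beta = c(llva_logmar = -4.6),
                               intercept = 25.5,
                               sd_patient = 2, sd_eye = 1, sd_resid = 1,
                               bcva_llva_corr = 0.8,
                               outcome = "ms_db", seed = 1) {
  set.seed(seed)
  n_eyes_per <- 1L + stats::rbinom(n_patients, 1L, p_two_eyes)
  pid <- rep(sprintf("P%04d", seq_len(n_patients)), n_eyes_per)
  eye <- unlist(lapply(n_eyes_per, function(k)
    if (k == 2L) c("right", "left") else sample(c("right", "left"), 1)))
  n <- length(pid)
  llva <- stats::rnorm(n, 0.32, 0.12)
  bcva <- 0.02 + 0.12 * (bcva_llva_corr * (llva - 0.32) / 0.12 +
                           sqrt(1 - bcva_llva_corr^2) * stats::rnorm(n))
  tab <- data.frame(
    patient_id = pid, eye = eye,
    bcva_logmar = bcva, llva_logmar = llva,
    log10_bcea95 = stats::rnorm(n, -0.8, 0.8),
    lens_status = sample(c("phakic", "pseudophakic"), n, replace = TRUE,
                         prob = c(0.648, 0.352)),
    smoking = sample(c("Never smoked", "Ex-smoker", "Current smoker"), n,
                     replace = TRUE, prob = c(0.421, 0.498, 0.081)),
    sex = sample(c("female", "male"), n, replace = TRUE,
                 prob = c(0.64, 0.36)))
  tab <- as_covariate_factors(tab)
  bad <- setdiff(names(beta), names(tab))
  if (length(bad))
    stop(sprintf("beta names not in table: %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  eta <- intercept
  for (nm in names(beta)) eta <- eta + beta[[nm]] * tab[[nm]]
  u <- stats::rnorm(n_patients, 0, sd_patient)
  tab[[outcome]] <- eta + rep(u, n_eyes_per) +
    stats::rnorm(n, 0, sd_eye) + stats::rnorm(n, 0, sd_resid)
  list(table = tab,
       truth = list(beta = beta, intercept = intercept,
                    sd_patient = sd_patient, sd_eye = sd_eye,
                    sd_resid = sd_resid, outcome = outcome))
}
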
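test_that("the generator is fully determined by its seed", {
  cfg <- sim_config(n_patients = 12, seed = 7)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(lapply(a$exams, `[[`, "thresholds"),
                   lapply(b$exams, `[[`, "thresholds"))
  expect_identical(a$covariates, b$covariates)
  expect_identical(a$truth$eyes, b$truth$eyes)
  c_ <- simulate_cohort(sim_config(n_patients = 12, seed = 8))
  expect_false(identical(lapply(a$exams, `[[`, "thresholds"),
                         lapply(c_$exams, `[[`, "thresholds")))
})

test_that("the noise-free limit collapses to the rounded base sensitivity", {
  cfg <- sim_config(n_patients = 5, sigma_patient = 0, sigma_eye = 0,
                    sigma_test = 0, ecc_slope = 0,
                    scotoma = list(rate = 0, depth_range = c(5, 20),
                                   radius_range = c(0.8, 2),
                                   center_radius = 5),
                    base_sensitivity = 26.3, seed = 1)
  coh <- simulate_cohort(cfg)
  for (e in coh$exams) {
    expect_true(all(e$thresholds == 26))
    expect_equal(mean_sensitivity(e), 26)
  }
  expect_equal(coh$truth$eyes$true_ms, rep(26.3, nrow(coh$truth$eyes)))
})

test_that("cohort structure and covariate frequencies match the config", {
  coh <- simulate_cohort(sim_config(n_patients = 400, seed = 21))
  cov <- coh$covariates
  eyes_per <- table(cov$patient_id)
  expect_true(all(eyes_per %in% 1:2))
  p2 <- mean(eyes_per == 2)
  expect_lt(abs(p2 - 0.31), 4 * sqrt(0.31 * 0.69 / 400))
  expect_lt(abs(mean(cov$lens_status == "pseudophakic") - 0.352), 0.08)
  per_pat <- cov[!duplicated(cov$patient_id), ]
  expect_lt(abs(mean(per_pat$sex == "female") - 0.64), 0.08)
  expect_lt(abs(mean(per_pat$smoking == "Ex-smoker") - 0.498), 0.08)
  expect_equal(levels(cov$smoking),
               c("Never smoked", "Ex-smoker", "Current smoker"))
})

test_that("simulated exams carry plausible iAMD sensitivities", {
  coh <- simulate_cohort(sim_config(seed = 4))
  ms <- vapply(coh$exams, mean_sensitivity, numeric(1))
  expect_gt(length(ms), 189)          # 1-2 eyes per patient
  expect_lt(abs(median(ms) - 24.2), 1.5)
  expect_true(all(ms >= 0 & ms <= 36))
  # thresholds are integers on the device range
  thr <- unlist(lapply(coh$exams, `[[`, "thresholds"))
  expect_true(all(thr == round(thr) & thr >= 0 & thr <= 36))
})

test_that("oracle volumes agree with exact polygon moments", {
  cfg <- sim_config(n_patients = 1, p_two_eyes = 0, sigma_patient = 0,
                    sigma_eye = 0, sigma_test = 0, base_sensitivity = 25,
                    ecc_slope = 0,
                    scotoma = list(rate = 0, depth_range = c(5, 20),
                                   radius_range = c(0.8, 2),
                                   center_radius = 5), seed = 2)
  coh <- simulate_cohort(cfg)
  pid <- coh$truth$eyes$patient_id[1]; eye <- coh$truth$eyes$eye[1]
  expect_equal(oracle_vtot(coh$truth, pid, eye, resolution = 0.02),
               25 * 68, tolerance = 1e-9)
  # quadratic falloff: exact second moments of the hull polygon
  cfg2 <- sim_config(n_patients = 1, p_two_eyes = 0, sigma_patient = 0,
                     sigma_eye = 0, sigma_test = 0, base_sensitivity = 25,
                     ecc_slope = 0.06,
                     scotoma = list(rate = 0, depth_range = c(5, 20),
                                    radius_range = c(0.8, 2),
                                    center_radius = 5), seed = 2)
  coh2 <- simulate_cohort(cfg2)
  hull <- convex_hull(pinnacle_grid()$points)
  mom <- hovmp:::polygon_moments(hull)
  expected <- 25 * mom$area - 0.06 * (mom$ix + mom$iy)
  expect_equal(oracle_vtot(coh2$truth, pid, eye, resolution = 0.02),
               expected, tolerance = 1e-5)
})

test_that("TPS volume tracks the oracle volume for smooth truths", {
  cfg <- sim_config(n_patients = 6, sigma_test = 0,
                    scotoma = list(rate = 0, depth_range = c(5, 20),
                                   radius_range = c(0.8, 2),
                                   center_radius = 5), seed = 9)
  coh <- simulate_cohort(cfg)
  for (k in seq_len(3)) {
    e <- coh$exams[[k]]
    v_tps <- compute_vtot(e, "cartesian", check_convergence = FALSE)$value
    v_true <- oracle_vtot(coh$truth, e$patient_id, e$eye, resolution = 0.02)
    expect_equal(v_tps, v_true, tolerance = 0.01)
  }
})

test_that("fixation simulation is seeded and matches its parameters", {
  s1 <- simulate_fixation(1, 2, 0.9, 2e4, seed = 5)
  s2 <- simulate_fixation(1, 2, 0.9, 2e4, seed = 5)
  expect_identical(s1, s2)
  expect_lt(abs(cor(s1[, 1], s1[, 2]) - 0.9), 0.02)
  expect_lt(abs(sd(s1[, 1]) - 1), 0.03)
  expect_lt(abs(sd(s1[, 2]) - 2), 0.06)
  expect_error(simulate_fixation(0, 1, 0, 10), "positive")
  expect_error(simulate_fixation(1, 1, 1, 10), "rho")
})
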
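# Estimators: exact inversion on noiseless data, error paths, drift
# invariance.

test_that("activation constant is recovered exactly from noiseless data", {
  s <- gen_dose_response(doses_Gy = c(0, 0.5, 1, 1.5, 2), noise = no_noise())
  f <- fit_activation_constant(s)
  expect_equal(f$k_per_Gy, 0.21, tolerance = 1e-9)
  expect_equal(f$r_squared, 1, tolerance = 1e-9)
  expect_equal(f$n_points, 4L)
  # a different generating constant is recovered just as exactly
  p <- switch_parameters(k_act_per_Gy = 0.0183)
  s2 <- gen_dose_response(p, doses_Gy = c(0, 2, 3, 5, 10), noise = no_noise())
  expect_equal(fit_activation_constant(s2)$k_per_Gy, 0.0183,
               tolerance = 1e-9)
})

test_that("activation fit works on absorbance readout through two-point mixing", {
  s <- gen_dose_response(doses_Gy = c(0, 0.5, 1, 1.5, 2),
                         readout = "absorbance_367nm", noise = no_noise())
  expect_equal(fit_activation_constant(s)$k_per_Gy, 0.21, tolerance = 1e-9)
})

test_that("activation fit rejects bad series", {
  expect_error(
    fit_activation_constant(
      dose_response_series(c(0, 1), c(0.1, 0.3))),
    "insufficient|3 non-zero")
  # a point at the endpoint violates the open interval
  expect_error(
    fit_activation_constant(
      dose_response_series(c(0, 1, 2, 3), c(0.1, 0.3, 1.0, 0.5))),
    "open interval")
})

test_that("intercept option returns a near-zero intercept on model data", {
  s <- gen_dose_response(doses_Gy = c(0, 0.5, 1, 1.5, 2), noise = no_noise())
  f <- fit_activation_constant(s, intercept = TRUE)
  expect_equal(f$k_per_Gy, 0.21, tolerance = 1e-8)
  expect_true(f$intercept_used)
})

test_that("G-value estimator reproduces the hand-computed anchor", {
  # constructed inputs: irradiated +18.0 uM, control +1.2 uM at 2 Gy from a
  # 50 uM pool -> (18 - 1.2)/2 = 8.4 umol/J -> 81.05 per 100 eV
  s <- dose_response_series(c(0, 2), c(0.10, 0.10 + 18.0 / 50),
                            control_values = c(0.10, 0.10 + 1.2 / 50),
                            timestamps_h = c(0, 0.5))
  r <- fit_g_value(s, initial_cis_uM = 50, dose_Gy = 2)
  expect_equal(r$g$value_umol_per_J, 8.4, tolerance = 1e-9)
  expect_equal(r$g$value_per_100ev, umol_per_J_to_g_per_100ev(8.4),
               tolerance = 1e-9)
  expect_equal(round(r$g$value_per_100ev), 81)
  expect_true(r$corrected_for_thermal)
})

test_that("thermal correction removes pure drift and common drift", {
  # control drift equal to the irradiated increase: everything is thermal
  s <- dose_response_series(c(0, 2), c(0.10, 0.22),
                            control_values = c(0.10, 0.22),
                            timestamps_h = c(0, 1))
  expect_equal(fit_g_value(s, 50, 2)$g$value_umol_per_J, 0)
  # invariance: adding a common drift to both plates changes nothing
  s1 <- dose_response_series(c(0, 2), c(0.10, 0.46),
                             control_values = c(0.10, 0.13))
  s2 <- dose_response_series(c(0, 2), c(0.10, 0.46 + 0.05),
                             control_values = c(0.10, 0.13 + 0.05))
  expect_equal(fit_g_value(s2, 50, 2)$g$value_umol_per_J,
               fit_g_value(s1, 50, 2)$g$value_umol_per_J)
})

test_that("G-value estimator flags missing controls and uncorrected use", {
  s <- dose_response_series(c(0, 2), c(0.10, 0.46))
  expect_error(fit_g_value(s, 50, 2), "control")
  r <- fit_g_value(s, 50, 2, correct_thermal = FALSE)
  expect_false(r$corrected_for_thermal)
  expect_equal(r$g$value_umol_per_J, 0.36 * 50 / 2)
})

test_that("coumarin estimator inverts the generator exactly at zero noise", {
  a <- gen_coumarin_assay(noise = no_noise())
  g <- fit_g_ho(a)
  expect_equal(g$value_umol_per_J, 0.280, tolerance = 1e-9)
  # hand arithmetic: slope 8.68e-3 uM/Gy at yield 0.031 -> 0.280
  expect_equal(attr(g, "g_7ohc_umol_per_J"), 0.031 * 0.280, tolerance = 1e-9)
  # XR preset
  expect_equal(fit_g_ho(gen_coumarin_assay(ir_source("XR"),
                                           noise = no_noise()))$value_umol_per_J,
               0.200, tolerance = 1e-9)
})

test_that("coumarin estimator scales inversely with the conversion yield", {
  a <- gen_coumarin_assay(noise = no_noise())
  a2 <- coumarin_assay(a$doses_Gy, a$fluorescence_au, a$standard_curve,
                       conversion_yield = 2 * a$conversion_yield)
  expect_equal(fit_g_ho(a2)$value_umol_per_J,
               fit_g_ho(a)$value_umol_per_J / 2, tolerance = 1e-9)
})

test_that("coumarin estimator handles flat and degenerate input", {
  flat <- coumarin_assay(c(0, 5, 10), c(0, 0, 0))
  expect_warning(g <- fit_g_ho(flat), "non-positive")
  expect_equal(g$value_umol_per_J, 0)
  expect_error(coumarin_assay(c(0, 5), c(1, 2),
                              standard_curve = c(0, 0)), "degenerate")
  expect_error(fit_g_ho(coumarin_assay(c(0, 5), c(0, 1))), "3 distinct")
})

test_that("enhancement profile computes G(c)/G(0) - 1 and finds the maximum", {
  flatp <- enhancement_profile(c(`0` = 0.28, `100` = 0.28, `500` = 0.28))
  expect_true(all(flatp$profile$enhancement == 0))
  p <- enhancement_profile(c(`0` = 0.280, `500` = 0.336))
  expect_equal(p$max_enhancement, 0.20, tolerance = 1e-12)
  expect_equal(p$argmax_concentration_uM, 500)
  p2 <- enhancement_profile(c(`0` = 0.200, `200` = 0.266))
  expect_equal(p2$max_enhancement, 0.33, tolerance = 1e-12)
  expect_error(enhancement_profile(c(`10` = 0.3, `500` = 0.4)), "baseline")
})

test_that("thermal half-life is recovered exactly from a noiseless course", {
  tc <- gen_relaxation_course(noise = no_noise())
  expect_equal(fit_thermal_half_life(tc)$half_life_h, 2.3, tolerance = 1e-9)
  p <- switch_parameters(thermal_half_life_h = 6)
  tc6 <- gen_relaxation_course(p, duration_h = 12, noise = no_noise())
  expect_equal(fit_thermal_half_life(tc6)$half_life_h, 6, tolerance = 1e-9)
})

test_that("half-life fit filters saturated points and rejects flat courses", {
  tc <- gen_relaxation_course(noise = no_noise())
  tc$trans_fraction[8] <- 1
  expect_warning(f <- fit_thermal_half_life(tc), "filtered")
  expect_equal(f$n_points, 7L)
  flat <- data.frame(time_h = 0:5, trans_fraction = rep(0.2, 6))
  expect_error(fit_thermal_half_life(flat), "insufficient|increase")
  short <- data.frame(time_h = 0:2, trans_fraction = c(0.1, 0.2, 0.3))
  expect_error(fit_thermal_half_life(short), "at least 4")
})

test_that("efficiency model coefficients are recovered exactly", {
  d <- c(2, 5, 10, 20)
  y <- -0.036 * log(d) + 0.1304
  f <- fit_efficiency_model(stats::setNames(y, d))
  expect_equal(f$a, -0.036, tolerance = 1e-12)
  expect_equal(f$b, 0.1304, tolerance = 1e-12)
  expect_equal(f$r_squared, 1)
  expect_error(fit_efficiency_model(stats::setNames(y[1:2], d[1:2])),
               "3 distinct")
  expect_error(fit_efficiency_model(stats::setNames(c(y, 0.1), c(d, 0))),
               "positive")
})
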
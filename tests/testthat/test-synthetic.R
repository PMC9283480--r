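# Generators: seeded determinism, zero-noise exactness, spectrum structure,
# and full-pipeline parameter recovery on noisy ensembles.

test_that("generators are byte-identical under the same seed", {
  n <- assay_noise(seed = 42)
  expect_identical(gen_dose_response(noise = n, replicates = 3),
                   gen_dose_response(noise = n, replicates = 3))
  expect_identical(gen_relaxation_course(noise = n),
                   gen_relaxation_course(noise = n))
  expect_identical(gen_coumarin_assay(noise = n),
                   gen_coumarin_assay(noise = n))
  expect_identical(gen_gd_enhancement_table(noise = n),
                   gen_gd_enhancement_table(noise = n))
  # different seeds differ
  expect_false(identical(gen_relaxation_course(noise = assay_noise(seed = 1)),
                         gen_relaxation_course(noise = assay_noise(seed = 2))))
})

test_that("seeded generation restores the caller's RNG state", {
  set.seed(123)
  before <- .Random.seed
  invisible(gen_coumarin_assay(noise = assay_noise(seed = 7)))
  expect_identical(.Random.seed, before)
})

test_that("child seeds are deterministic and within integer range", {
  s1 <- child_seeds(99, 10)
  s2 <- child_seeds(99, 10)
  expect_identical(s1, s2)
  expect_true(all(s1 > 0 & s1 < 2^31))
  expect_equal(length(unique(s1)), 10)
})

test_that("zero-noise dose response sits exactly on the monoexponential", {
  doses <- c(0, 2, 3, 5, 10)
  s <- gen_dose_response(doses_Gy = doses, noise = no_noise())
  expect_equal(s$irradiated, 1 - 0.90 * exp(-0.21 * doses), tolerance = 1e-12)
  expect_equal(s$control, rep(0.10, 5))  # no lag, no relaxation
  expect_equal(attr(s, "a0"), 0.10)
  expect_equal(attr(s, "a_inf"), 1)
})

test_that("with a measurement lag both plates relax and the control drifts", {
  s <- gen_dose_response(doses_Gy = c(0, 2, 3, 5, 10), lag_h = 0.5,
                         noise = no_noise())
  # control follows pure thermal relaxation at the matched timestamps
  expected_ctrl <- 1 - 0.90 * exp(-log(2) * s$time_h / 2.3)
  expect_equal(s$control, expected_ctrl, tolerance = 1e-12)
  expect_true(all(diff(s$control) > 0))
  # irradiated plate sits above the control everywhere past dose 0
  expect_true(all(s$irradiated[-1] > s$control[-1]))
})

test_that("zero-noise relaxation course is the exact exponential", {
  tc <- gen_relaxation_course(noise = no_noise())
  expect_equal(tc$trans_fraction,
               1 - 0.90 * exp(-log(2) * tc$time_h / 2.3), tolerance = 1e-12)
})

test_that("zero-noise coumarin assay is linear in dose", {
  a <- gen_coumarin_assay(noise = no_noise())
  conc <- (a$fluorescence_au - a$standard_curve["intercept"]) /
    a$standard_curve["slope"]
  expect_equal(unname(conc), 0.031 * 0.280 * a$doses_Gy, tolerance = 1e-12)
})

test_that("Gd table always carries the baseline and reproduces the anchors", {
  tab <- gen_gd_enhancement_table(noise = no_noise())
  expect_true(0 %in% tab$gd_concentration_uM)
  expect_equal(tab$g_ho_umol_per_J[tab$gd_concentration_uM == 0], 0.280)
  expect_equal(tab$g_ho_umol_per_J[tab$gd_concentration_uM == 500],
               0.280 * 1.20)
  # baseline prepended when omitted
  tab2 <- gen_gd_enhancement_table(concentrations_uM = c(100, 500),
                                   noise = no_noise())
  expect_equal(tab2$gd_concentration_uM[1], 0)
})

test_that("spectra are weighted sums of the pure bands and peak correctly", {
  m <- spectrum_model()
  pure_trans <- gen_absorbance_spectrum(isomer_state(1), m, no_noise())
  expect_equal(pure_trans$wavelength_nm[which.max(pure_trans$absorbance)],
               367, tolerance = 2)
  pure_cis <- gen_absorbance_spectrum(isomer_state(0), m, no_noise())
  expect_equal(pure_cis$wavelength_nm[which.max(pure_cis$absorbance)],
               322, tolerance = 2)
  mix <- gen_absorbance_spectrum(isomer_state(0.4), m, no_noise())
  expect_equal(mix$absorbance,
               0.6 * pure_cis$absorbance + 0.4 * pure_trans$absorbance,
               tolerance = 1e-12)
  expect_true(all(mix$absorbance >= 0))
})

test_that("367 nm readout maps back to the trans fraction by two-point mixing", {
  m <- spectrum_model()
  ends <- pure_absorbance_367(m)
  for (tr in c(0.1, 0.37, 0.9)) {
    sp <- gen_absorbance_spectrum(isomer_state(tr), m, no_noise())
    a367 <- sp$absorbance[sp$wavelength_nm == 367][1]
    # grid may not contain 367 exactly; interpolate
    if (is.na(a367)) a367 <- stats::approx(sp$wavelength_nm, sp$absorbance,
                                           367)$y
    expect_equal(absorbance_to_trans(a367, ends["cis"], ends["trans"]),
                 c(cis = tr), tolerance = 1e-3)
  }
})

test_that("noisy ensembles recover the generating parameters without bias", {
  # generate -> fit over 200 seeded replicates; the ensemble mean must sit
  # within 2 Monte-Carlo standard errors of the generating value
  n_rep <- 200
  seeds <- child_seeds(2024, 4 * n_rep)
  check_recovery <- function(est, truth) {
    mc_se <- stats::sd(est) / sqrt(length(est))
    expect_lt(abs(mean(est) - truth), 2 * mc_se + 1e-12)
  }

  k_hat <- vapply(seq_len(n_rep), function(i) {
    s <- gen_dose_response(doses_Gy = c(0, 0.5, 1, 1.5, 2),
                           noise = assay_noise(fraction_sigma = 0.018,
                                               seed = seeds[i]),
                           replicates = 3)
    fit_activation_constant(s)$k_per_Gy
  }, numeric(1))
  # the log transform carries a second-order (Jensen) bias of order
  # sigma^2 / (At - Ainf)^2 ~ 1e-4; require the bias to stay well below
  # 0.5% of k, i.e. 40x smaller than the experimental +/- 0.02 band
  expect_lt(abs(mean(k_hat) - 0.21), 0.001)

  t_hat <- vapply(seq_len(n_rep), function(i) {
    tc <- gen_relaxation_course(noise = assay_noise(fraction_sigma = 0.01,
                                                    seed = seeds[n_rep + i]))
    fit_thermal_half_life(tc)$half_life_h
  }, numeric(1))
  expect_lt(abs(mean(t_hat) - 2.3) / 2.3, 0.10)

  g_hat <- vapply(seq_len(n_rep), function(i) {
    a <- gen_coumarin_assay(noise = assay_noise(fluorescence_sigma_rel = 0.03,
                                                seed = seeds[2 * n_rep + i]))
    fit_g_ho(a)$value_umol_per_J
  }, numeric(1))
  check_recovery(g_hat, 0.280)

  ab <- vapply(seq_len(n_rep), function(i) {
    d <- c(2, 5, 10, 20)
    y <- -0.036 * log(d) + 0.1304 +
      .rnorm_seeded(length(d), 0.002, seeds[3 * n_rep + i])
    f <- fit_efficiency_model(stats::setNames(y, d))
    c(f$a, f$b)
  }, numeric(2))
  check_recovery(ab[1, ], -0.036)
  check_recovery(ab[2, ], 0.1304)
})
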
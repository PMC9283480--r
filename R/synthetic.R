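# Seeded generators for every assay the estimators consume. One root seed,
# per-assay child streams derived deterministically; identical seed and
# parameters give bit-identical output.

#' Assay noise model
#'
#' Noise magnitudes for the synthetic generators: additive Gaussian SDs on
#' absorbance (OD units) and on fractions (clipped to [0, 1]), and a
#' multiplicative Gaussian SD on fluorescence. Defaults give triplicate
#' scatter of roughly 2-5% of the dynamic range, the scale typical of the
#' plate assays being emulated. A `NULL` seed leaves the RNG state alone.
#'
#' @param absorbance_sigma Additive SD on absorbance, OD; default 0.005.
#' @param fraction_sigma Additive SD on isomer fractions; default 0.01.
#' @param fluorescence_sigma_rel Relative SD on fluorescence; default 0.03.
#' @param seed Integer seed, or `NULL`.
#' @return An `assay_noise` object.
#' @export
assay_noise <- function(absorbance_sigma = 0.005, fraction_sigma = 0.01,
                        fluorescence_sigma_rel = 0.03, seed = NULL) {
  stopifnot(absorbance_sigma >= 0, fraction_sigma >= 0,
            fluorescence_sigma_rel >= 0)
  structure(
    list(absorbance_sigma = absorbance_sigma,
         fraction_sigma = fraction_sigma,
         fluorescence_sigma_rel = fluorescence_sigma_rel,
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "assay_noise"
  )
}

#' Zero-noise model
#' @rdname assay_noise
#' @export
no_noise <- function() assay_noise(0, 0, 0, seed = NULL)

# Evaluate expr under a temporary RNG state seeded with `seed`; the caller's
# RNG state is restored afterwards. NULL seed evaluates in place.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Deterministic child seeds from a root seed
#'
#' Derives `n` independent sub-stream seeds from one root seed, so replicate
#' ensembles are reproducible from a single integer.
#'
#' @param root_seed Integer root seed.
#' @param n Number of child seeds.
#' @return Integer vector of length `n`, each below 2^31.
#' @export
child_seeds <- function(root_seed, n) {
  .with_seed(as.integer(root_seed), sample.int(.Machine$integer.max - 1L, n))
}

.clip01 <- function(x) pmin(pmax(x, 0), 1)

#' Simulate a paired irradiated/control dose-response assay
#'
#' Emulates the two-plate design: both plates start at the photostationary
#' composition; between consecutive measurements (spaced `lag_h` hours) both
#' plates relax thermally, and the irradiated plate additionally receives
#' the next dose increment. Measurement noise is added per replicate and
#' replicates are averaged, as plate experiments report means.
#'
#' @param params A [switch_parameters()].
#' @param source,conditions Irradiation source and solution conditions.
#' @param doses_Gy Non-decreasing cumulative doses starting at 0.
#' @param readout `"trans_fraction"` or `"absorbance_367nm"`.
#' @param noise An [assay_noise()].
#' @param lag_h Time between consecutive measurements, hours; default 0.
#' @param replicates Number of replicate wells averaged; default 1.
#' @param spectrum A [spectrum_model()] supplying the pure-isomer 367 nm
#'   absorbances when `readout = "absorbance_367nm"`.
#' @return A [dose_response_series()]; the generating parameters are stored
#'   in attribute `generating`.
#' @export
gen_dose_response <- function(params = switch_parameters(),
                              source = ir_source("GR"),
                              conditions = solution_conditions(),
                              doses_Gy = c(0, 2, 3, 5, 10),
                              readout = c("trans_fraction",
                                          "absorbance_367nm"),
                              noise = no_noise(),
                              lag_h = 0,
                              replicates = 1,
                              spectrum = spectrum_model()) {
  readout <- match.arg(readout)
  if (is.unsorted(doses_Gy) || doses_Gy[1] != 0) {
    stop("`doses_Gy` must be non-decreasing and start at 0", call. = FALSE)
  }
  if (is.character(source)) source <- ir_source(source)
  n <- length(doses_Gy)
  trans0 <- 1 - params$pss1_cis_fraction

  irr <- isomer_state(trans0)
  ctrl <- isomer_state(trans0)
  tr_irr <- tr_ctrl <- numeric(n)
  tr_irr[1] <- irr$trans_fraction
  tr_ctrl[1] <- ctrl$trans_fraction
  for (i in 2:n) {
    irr <- thermal_relax(irr, lag_h, params)
    ctrl <- thermal_relax(ctrl, lag_h, params)
    irr <- radiation_activate(irr, doses_Gy[i] - doses_Gy[i - 1],
                              source, conditions, params)
    tr_irr[i] <- irr$trans_fraction
    tr_ctrl[i] <- ctrl$trans_fraction
  }
  timestamps <- lag_h * (seq_len(n) - 1)

  if (readout == "trans_fraction") {
    clean_irr <- tr_irr; clean_ctrl <- tr_ctrl
    sigma <- noise$fraction_sigma
    a0 <- trans0; a_inf <- 1
  } else {
    ends <- pure_absorbance_367(spectrum)
    clean_irr <- ends["cis"] + tr_irr * (ends["trans"] - ends["cis"])
    clean_ctrl <- ends["cis"] + tr_ctrl * (ends["trans"] - ends["cis"])
    sigma <- noise$absorbance_sigma
    a0 <- unname(ends["cis"] + trans0 * (ends["trans"] - ends["cis"]))
    a_inf <- unname(ends["trans"])
  }

  noisy <- .with_seed(noise$seed, {
    irr_mat <- replicate(replicates, clean_irr + stats::rnorm(n, 0, sigma))
    ctrl_mat <- replicate(replicates, clean_ctrl + stats::rnorm(n, 0, sigma))
    if (readout == "trans_fraction") {
      irr_mat <- .clip01(irr_mat); ctrl_mat <- .clip01(ctrl_mat)
    }
    list(irr = rowMeans(irr_mat), ctrl = rowMeans(ctrl_mat))
  })

  out <- dose_response_series(doses_Gy, noisy$irr, noisy$ctrl, timestamps,
                              readout, a0 = a0, a_inf = a_inf)
  attr(out, "generating") <- list(params = params, source = source$name,
                                  gas = conditions$gas, lag_h = lag_h,
                                  replicates = replicates,
                                  seed = noise$seed)
  out
}

#' Simulate a thermal relaxation time course
#'
#' First-order dark relaxation from the photostationary state sampled at
#' evenly spaced times, with additive fraction noise.
#'
#' @param params A [switch_parameters()].
#' @param duration_h Course length, hours; default 8.
#' @param n_points Number of time points; default 8.
#' @param noise An [assay_noise()].
#' @param start_trans Starting trans fraction; defaults to
#'   `1 - pss1_cis_fraction`.
#' @return Data.frame with columns `time_h` and `trans_fraction`.
#' @export
gen_relaxation_course <- function(params = switch_parameters(),
                                  duration_h = 8, n_points = 8,
                                  noise = no_noise(),
                                  start_trans = NULL) {
  if (is.null(start_trans)) start_trans <- 1 - params$pss1_cis_fraction
  t <- seq(0, duration_h, length.out = n_points)
  clean <- 1 - (1 - start_trans) *
    exp(-log(2) * t / params$thermal_half_life_h)
  tr <- .with_seed(noise$seed,
                   .clip01(clean + stats::rnorm(n_points, 0,
                                                noise$fraction_sigma)))
  data.frame(time_h = t, trans_fraction = tr)
}

#' Simulate a coumarin dosimetry assay
#'
#' 7-OH-coumarin concentration grows linearly in dose as
#' `conversion_yield * G_eff(HO.) * dose`; fluorescence follows the standard
#' curve with multiplicative noise.
#'
#' @param source,conditions Irradiation source and solution conditions.
#' @param doses_Gy Doses; default the 0-40 Gy dosimetry schedule.
#' @param standard_curve `c(slope, intercept)` of fluorescence vs uM.
#' @param noise An [assay_noise()].
#' @param conversion_yield Coumarin to 7-OH-coumarin yield; default 0.031.
#' @return A [coumarin_assay()], generating parameters in attribute
#'   `generating`.
#' @export
gen_coumarin_assay <- function(source = ir_source("GR"),
                               conditions = solution_conditions(),
                               doses_Gy = c(0, 2, 5, 10, 15, 20, 25, 30, 40),
                               standard_curve = c(slope = 1000, intercept = 0),
                               noise = no_noise(),
                               conversion_yield = 0.031) {
  if (is.character(source)) source <- ir_source(source)
  g_eff <- effective_g_ho(source, conditions)$value_umol_per_J
  conc_7ohc <- conversion_yield * g_eff * doses_Gy
  clean <- standard_curve[1] * conc_7ohc + standard_curve[2]
  fl <- .with_seed(noise$seed,
                   clean * (1 + stats::rnorm(length(doses_Gy), 0,
                                             noise$fluorescence_sigma_rel)))
  out <- coumarin_assay(doses_Gy, unname(fl), standard_curve,
                        conversion_yield,
                        conditions$gd_concentration_uM)
  attr(out, "generating") <- list(source = source$name, gas = conditions$gas,
                                  g_eff_umol_per_J = g_eff, seed = noise$seed)
  out
}

#' Simulate a Gd3+ enhancement table
#'
#' Measured-style G(HO.) at a series of Gd3+ concentrations, generated from
#' the source's built-in anchor curve, with optional relative noise
#' (`fluorescence_sigma_rel`, as these yields derive from fluorescence
#' assays). Always includes the concentration-0 baseline.
#'
#' @param source Radiation source or preset name.
#' @param concentrations_uM Gd3+ concentrations; 0 is prepended if missing.
#' @param noise An [assay_noise()].
#' @param curve Optional [gd_curve()] override.
#' @return Data.frame with columns `gd_concentration_uM` and
#'   `g_ho_umol_per_J`.
#' @export
gen_gd_enhancement_table <- function(source = ir_source("GR"),
                                     concentrations_uM = c(0, 10, 25, 100,
                                                           200, 500, 1000,
                                                           2000),
                                     noise = no_noise(),
                                     curve = NULL) {
  if (is.character(source)) source <- ir_source(source)
  if (!0 %in% concentrations_uM) {
    concentrations_uM <- c(0, concentrations_uM)
  }
  if (is.null(curve)) curve <- gd_curve(source$name)
  g <- source$g_ho_base * (1 + gd_enhancement(concentrations_uM, curve))
  g <- .with_seed(noise$seed,
                  g * (1 + stats::rnorm(length(g), 0,
                                        noise$fluorescence_sigma_rel)))
  data.frame(gd_concentration_uM = concentrations_uM,
             g_ho_umol_per_J = g)
}

#' Two-band spectrum model for the pure isomers
#'
#' Gaussian absorption bands for the pi-pi* transitions of the two isomers:
#' cis centred at 322 nm, trans at 367 nm with much higher peak intensity.
#' Only the 367 nm two-point mixing is load-bearing for inference; the full
#' band shapes exist so simulated spectra look like spectra.
#'
#' @param band_centers_nm Named `c(cis=, trans=)` band centres.
#' @param band_widths_nm Named Gaussian SDs, nm.
#' @param peak_extinctions Named peak absorbances of the pure isomers at a
#'   50 uM reference concentration.
#' @param wavelength_grid_nm Wavelengths the spectrum is evaluated on.
#' @return A `spectrum_model` object.
#' @export
spectrum_model <- function(band_centers_nm = c(cis = 322, trans = 367),
                           band_widths_nm = c(cis = 30, trans = 35),
                           peak_extinctions = c(cis = 0.35, trans = 1.0),
                           wavelength_grid_nm = seq(250, 550, by = 1)) {
  stopifnot(all(band_widths_nm > 0), all(peak_extinctions > 0))
  structure(
    list(band_centers_nm = band_centers_nm,
         band_widths_nm = band_widths_nm,
         peak_extinctions = peak_extinctions,
         wavelength_grid_nm = wavelength_grid_nm),
    class = "spectrum_model"
  )
}

.pure_band <- function(lambda, model, which) {
  model$peak_extinctions[[which]] *
    exp(-0.5 * ((lambda - model$band_centers_nm[[which]]) /
                  model$band_widths_nm[[which]])^2)
}

#' Pure-isomer absorbances at 367 nm
#'
#' The two-point calibration used to map absorbance to trans fraction,
#' scaled to a 50 uM reference concentration.
#'
#' @param model A [spectrum_model()].
#' @return Named vector `c(cis=, trans=)`.
#' @export
pure_absorbance_367 <- function(model = spectrum_model()) {
  c(cis = .pure_band(367, model, "cis"),
    trans = .pure_band(367, model, "trans"))
}

#' Simulate an absorbance spectrum of an isomer mixture
#'
#' The mixture spectrum is the fraction-weighted sum of the two pure-isomer
#' Gaussian band spectra, scaled by concentration relative to the 50 uM
#' reference, plus additive absorbance noise.
#'
#' @param state An [isomer_state()].
#' @param model A [spectrum_model()].
#' @param noise An [assay_noise()].
#' @return Data.frame with columns `wavelength_nm` and `absorbance`.
#' @export
gen_absorbance_spectrum <- function(state, model = spectrum_model(),
                                    noise = no_noise()) {
  stopifnot(inherits(state, "isomer_state"))
  lambda <- model$wavelength_grid_nm
  scale <- state$total_concentration_uM / 50
  clean <- scale * (state$cis_fraction * .pure_band(lambda, model, "cis") +
                    state$trans_fraction * .pure_band(lambda, model, "trans"))
  a <- .with_seed(noise$seed,
                  pmax(clean + stats::rnorm(length(lambda), 0,
                                            noise$absorbance_sigma), 0))
  data.frame(wavelength_nm = lambda, absorbance = a)
}
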
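# Forward model of the radioswitch: photostationary start, first-order
# thermal back-relaxation, monoexponential activation in dose, the
# logarithmic dose-efficiency model, and Fenton/dose equivalence inversion.

#' Kinetic parameters of the radioswitch
#'
#' Bundles the constants of the cis-to-trans activation model: the activation
#' constant `k_act_per_Gy` (per Gy, defined at the reference HO. yield
#' `reference_g_ho`), the photostationary composition after UV preparation
#' (default 90% cis), the thermal back-relaxation half-life (default 2.3 h at
#' 37 C in PBS), and the coefficients of the empirical logarithmic
#' dose-efficiency model `Y = a ln(dose) + b` relating the per-concentration
#' G-value slope to dose.
#'
#' @param k_act_per_Gy Activation constant, Gy-1 (> 0); default 0.21 (gamma
#'   irradiation of the Gd-bearing switch).
#' @param pss1_cis_fraction Cis fraction at the photostationary state reached
#'   under 365 nm UV, in [0, 1]; default 0.90.
#' @param thermal_half_life_h Cis-to-trans dark-relaxation half-life, hours
#'   (> 0); default 2.3 (37 C, PBS). No Arrhenius scaling is applied:
#'   override for other temperatures.
#' @param reference_g_ho Effective G(HO.) at which `k_act_per_Gy` was
#'   measured, umol/J; default 0.280 (gamma, plain water).
#' @param efficiency_a,efficiency_b Coefficients of the dose-efficiency model
#'   in G-value per uM; defaults -0.036 and 0.1304.
#' @return A `switch_parameters` object.
#' @export
switch_parameters <- function(k_act_per_Gy = 0.21,
                              pss1_cis_fraction = 0.90,
                              thermal_half_life_h = 2.3,
                              reference_g_ho = 0.280,
                              efficiency_a = -0.036,
                              efficiency_b = 0.1304) {
  if (!is.numeric(k_act_per_Gy) || k_act_per_Gy <= 0) {
    stop("`k_act_per_Gy` must be positive", call. = FALSE)
  }
  if (pss1_cis_fraction < 0 || pss1_cis_fraction > 1) {
    stop("`pss1_cis_fraction` must be in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(thermal_half_life_h) || thermal_half_life_h <= 0) {
    stop("`thermal_half_life_h` must be positive", call. = FALSE)
  }
  if (!is.numeric(reference_g_ho) || reference_g_ho <= 0) {
    stop("`reference_g_ho` must be positive", call. = FALSE)
  }
  structure(
    list(k_act_per_Gy = k_act_per_Gy,
         pss1_cis_fraction = pss1_cis_fraction,
         thermal_half_life_h = thermal_half_life_h,
         reference_g_ho = reference_g_ho,
         efficiency_a = efficiency_a,
         efficiency_b = efficiency_b),
    class = "switch_parameters"
  )
}

#' @export
print.switch_parameters <- function(x, ...) {
  cat(sprintf(
    "<switch_parameters> k = %.3g /Gy (at G(HO.) = %.3g umol/J), PSS1 %.0f%% cis, t1/2 = %.3g h\n",
    x$k_act_per_Gy, x$reference_g_ho, 100 * x$pss1_cis_fraction,
    x$thermal_half_life_h))
  cat(sprintf("  efficiency model Y = %.4g ln(D) + %.4g (G-value/uM)\n",
              x$efficiency_a, x$efficiency_b))
  invisible(x)
}

#' Isomer composition state
#'
#' The composition of the switch solution at a point in time. There is no
#' third species: `cis_fraction = 1 - trans_fraction` by construction.
#'
#' @param trans_fraction Trans-isomer fraction in [0, 1].
#' @param total_concentration_uM Total switch concentration, uM (> 0).
#' @param time_h Timestamp, hours (>= 0).
#' @return An `isomer_state` object.
#' @examples
#' isomer_state(0.10)  # freshly prepared photostationary state
#' @export
isomer_state <- function(trans_fraction, total_concentration_uM = 50,
                         time_h = 0) {
  if (!is.numeric(trans_fraction) || trans_fraction < 0 || trans_fraction > 1) {
    stop("`trans_fraction` must be in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(total_concentration_uM) || total_concentration_uM <= 0) {
    stop("`total_concentration_uM` must be positive", call. = FALSE)
  }
  if (!is.numeric(time_h) || time_h < 0) {
    stop("`time_h` must be non-negative", call. = FALSE)
  }
  structure(
    list(trans_fraction = trans_fraction,
         cis_fraction = 1 - trans_fraction,
         total_concentration_uM = total_concentration_uM,
         time_h = time_h),
    class = "isomer_state"
  )
}

#' @export
print.isomer_state <- function(x, ...) {
  cat(sprintf("<isomer_state> t = %.3g h: %.1f%% trans / %.1f%% cis of %.4g uM\n",
              x$time_h, 100 * x$trans_fraction, 100 * x$cis_fraction,
              x$total_concentration_uM))
  invisible(x)
}

#' First-order thermal back-relaxation
#'
#' In the dark, the metastable cis isomer reverts to trans with first-order
#' kinetics: `trans(t) = 1 - (1 - trans0) exp(-ln2 t / t_half)`. The map is
#' a semigroup in elapsed time and the trans fraction never decreases.
#'
#' @param state An [isomer_state()].
#' @param elapsed_h Elapsed time, hours (>= 0).
#' @param params A [switch_parameters()] supplying the half-life.
#' @return The relaxed [isomer_state()], with `time_h` advanced.
#' @examples
#' thermal_relax(isomer_state(0), 2.3)$trans_fraction  # 0.5 after one t1/2
#' @export
thermal_relax <- function(state, elapsed_h, params = switch_parameters()) {
  stopifnot(inherits(state, "isomer_state"),
            inherits(params, "switch_parameters"))
  if (!is.numeric(elapsed_h) || elapsed_h < 0) {
    stop("`elapsed_h` must be non-negative", call. = FALSE)
  }
  new_trans <- 1 - (1 - state$trans_fraction) *
    exp(-log(2) * elapsed_h / params$thermal_half_life_h)
  isomer_state(new_trans, state$total_concentration_uM,
               state$time_h + elapsed_h)
}

#' Effective activation constant under given conditions
#'
#' The central modelling assumption: the activation constant scales linearly
#' with the effective hydroxyl-radical yield,
#' `k_eff = k_act_per_Gy * G_eff(HO.) / reference_g_ho`. Two exposures with
#' equal dose x G_eff products therefore produce identical states.
#'
#' @inheritParams radiation_activate
#' @return Effective activation constant, Gy-1.
#' @export
k_effective <- function(params = switch_parameters(),
                        source = ir_source("GR"),
                        conditions = solution_conditions()) {
  if (is.character(source)) source <- ir_source(source)
  g_eff <- effective_g_ho(source, conditions)$value_umol_per_J
  params$k_act_per_Gy * g_eff / params$reference_g_ho
}

#' Radiation-triggered cis-to-trans activation
#'
#' Monoexponential approach to the all-trans endpoint in cumulative dose:
#' `trans(D) = 1 - (1 - trans0) exp(-k_eff D)`, with `k_eff` from
#' [k_effective()]. The map is a semigroup in dose (dose a then dose b equals
#' a single dose a+b) and is monotone non-decreasing in dose.
#'
#' @param state An [isomer_state()].
#' @param dose_Gy Absorbed dose in Gy (>= 0).
#' @param source A [radiation_source()] or preset name; default `"GR"`.
#' @param conditions A [solution_conditions()]; default plain water.
#' @param params A [switch_parameters()].
#' @return The activated [isomer_state()].
#' @examples
#' radiation_activate(isomer_state(0.10), 2)$trans_fraction  # ~0.41
#' @export
radiation_activate <- function(state, dose_Gy,
                               source = ir_source("GR"),
                               conditions = solution_conditions(),
                               params = switch_parameters()) {
  stopifnot(inherits(state, "isomer_state"))
  if (!is.numeric(dose_Gy) || dose_Gy < 0) {
    stop("`dose_Gy` must be non-negative", call. = FALSE)
  }
  k_eff <- k_effective(params, source, conditions)
  new_trans <- 1 - (1 - state$trans_fraction) * exp(-k_eff * dose_Gy)
  isomer_state(new_trans, state$total_concentration_uM, state$time_h)
}

#' Predicted trans-isomer G-value from the dose-efficiency model
#'
#' The empirical logarithmic efficiency model: the per-concentration slope of
#' the trans-isomer G-value is `Y(D) = a ln(D) + b` (G-value per uM), so the
#' predicted yield at an initial cis concentration `c` is `c * Y(D)`. The
#' model is linear in concentration (stoichiometric, non-catalytic
#' conversion) and decreasing in dose for `a < 0`. It was fitted over
#' 2-20 Gy; a warning is issued outside that range, and a negative predicted
#' yield (beyond ~37 Gy with the defaults) is clipped at 0 with a warning.
#'
#' @param cis_concentration_uM Initial cis-isomer concentration, uM (> 0).
#' @param dose_Gy Dose in Gy (> 0; the model is logarithmic in dose).
#' @param params A [switch_parameters()].
#' @return Predicted G(trans) in molecules per 100 eV.
#' @examples
#' predict_g_trans(1, 1)    # the intercept, 0.1304
#' predict_g_trans(50, 2)   # ~5.27
#' @export
predict_g_trans <- function(cis_concentration_uM, dose_Gy,
                            params = switch_parameters()) {
  if (!is.numeric(cis_concentration_uM) || any(cis_concentration_uM <= 0)) {
    stop("`cis_concentration_uM` must be positive", call. = FALSE)
  }
  if (!is.numeric(dose_Gy) || any(dose_Gy <= 0)) {
    stop("`dose_Gy` must be positive (the efficiency model is logarithmic in dose)",
         call. = FALSE)
  }
  if (any(dose_Gy < 2 | dose_Gy > 20)) {
    warning("dose outside the 2-20 Gy range the efficiency model was fitted on")
  }
  g <- cis_concentration_uM *
    (params$efficiency_a * log(dose_Gy) + params$efficiency_b)
  if (any(g < 0)) {
    warning("efficiency model predicts a negative yield; clipping at 0")
    g <- pmax(g, 0)
  }
  g
}

#' Radiation-equivalent dose of a chemically induced trans jump
#'
#' Inverts the monoexponential activation model: an observed trans-fraction
#' increase (for instance from a Fenton reaction) maps onto the radiation
#' dose that would have produced it,
#' `D = -ln[(1 - trans_after) / (1 - trans_before)] / k_eff`. Round-trips
#' exactly with [radiation_activate()].
#'
#' @param trans_before,trans_after Trans fractions with
#'   `0 <= trans_before <= trans_after < 1`.
#' @param params A [switch_parameters()].
#' @param source,conditions Optional source/conditions defining `k_eff`;
#'   defaults give `k_eff = k_act_per_Gy`.
#' @return Equivalent dose in Gy.
#' @examples
#' fenton_equivalent_dose(0.167, 0.484)  # ~2.28 Gy
#' @export
fenton_equivalent_dose <- function(trans_before, trans_after,
                                   params = switch_parameters(),
                                   source = ir_source("GR"),
                                   conditions = solution_conditions()) {
  if (trans_before < 0 || trans_after < trans_before) {
    stop("need 0 <= trans_before <= trans_after", call. = FALSE)
  }
  if (trans_after >= 1) {
    stop("trans_after = 1 corresponds to an infinite equivalent dose",
         call. = FALSE)
  }
  k_eff <- k_effective(params, source, conditions)
  -log((1 - trans_after) / (1 - trans_before)) / k_eff
}
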
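# Estimators: activation constant, G-values with paired-control thermal
# correction, G(HO.) from the coumarin assay, Gd enhancement profile, thermal
# half-life, efficiency-model coefficients. Ordinary least squares
# throughout (stats::lm).

#' Paired irradiated/control dose-response series
#'
#' Measurements of isomer composition (or 367 nm absorbance) versus
#' cumulative dose on an irradiated plate, paired with a non-irradiated
#' control plate prepared identically and measured at the same timestamps so
#' thermal back-relaxation can be subtracted.
#'
#' @param doses_Gy Non-decreasing doses starting at 0.
#' @param irradiated_values Readout on the irradiated plate.
#' @param control_values Readout on the paired dark-control plate (may be
#'   `NULL` when no control was run).
#' @param timestamps_h Non-decreasing measurement times, hours.
#' @param readout `"trans_fraction"` or `"absorbance_367nm"`.
#' @param a0 Readout at dose 0 (the photostationary start); defaults to the
#'   first irradiated value.
#' @param a_inf Readout at full trans conversion; defaults to 1 for
#'   trans-fraction data and must be given for absorbance data.
#' @return A `dose_response_series` object (also a data.frame).
#' @export
dose_response_series <- function(doses_Gy, irradiated_values,
                                 control_values = NULL,
                                 timestamps_h = rep(0, length(doses_Gy)),
                                 readout = c("trans_fraction",
                                             "absorbance_367nm"),
                                 a0 = NULL, a_inf = NULL) {
  readout <- match.arg(readout)
  n <- length(doses_Gy)
  if (length(irradiated_values) != n || length(timestamps_h) != n ||
      (!is.null(control_values) && length(control_values) != n)) {
    stop("all columns must have the same length", call. = FALSE)
  }
  if (is.unsorted(doses_Gy) || doses_Gy[1] != 0) {
    stop("`doses_Gy` must be non-decreasing and start at 0", call. = FALSE)
  }
  if (is.unsorted(timestamps_h)) {
    stop("`timestamps_h` must be non-decreasing", call. = FALSE)
  }
  if (is.null(a0)) a0 <- irradiated_values[1]
  if (is.null(a_inf)) {
    if (readout == "trans_fraction") a_inf <- 1
    else stop("`a_inf` (absorbance at full conversion) is required for absorbance data",
              call. = FALSE)
  }
  df <- data.frame(dose_Gy = doses_Gy, irradiated = irradiated_values,
                   control = if (is.null(control_values)) NA_real_ else control_values,
                   time_h = timestamps_h)
  structure(df, readout = readout, a0 = a0, a_inf = a_inf,
            class = c("dose_response_series", "data.frame"))
}

#' Convert absorbance at 367 nm to a trans fraction
#'
#' Two-component Beer-Lambert mixing: at a wavelength where both pure
#' isomers have known absorbance, `trans = (A - A_cis) / (A_trans - A_cis)`.
#'
#' @param a Measured absorbance.
#' @param a_cis,a_trans Pure cis- and trans-isomer absorbances at the same
#'   wavelength and concentration (`a_trans != a_cis`).
#' @return Trans fraction(s).
#' @export
absorbance_to_trans <- function(a, a_cis, a_trans) {
  if (a_trans == a_cis) {
    stop("degenerate calibration: a_trans must differ from a_cis",
         call. = FALSE)
  }
  (a - a_cis) / (a_trans - a_cis)
}

#' Fit the activation constant from a dose-response series
#'
#' The monoexponential activation model linearises as
#' `ln[(A0 - Ainf) / (At - Ainf)] = k D`; the activation constant is the OLS
#' slope of that transform against dose, through the origin by default
#' (the transform is exactly 0 at dose 0). On noiseless model-generated data
#' the generating constant is recovered to numerical precision.
#'
#' @param series A [dose_response_series()].
#' @param intercept Include a free intercept (diagnostic option);
#'   default `FALSE`.
#' @return An `activation_fit` with fields `k_per_Gy`, `k_stderr`,
#'   `r_squared`, `n_points`, `dose_range_Gy`, `intercept_used`.
#' @export
fit_activation_constant <- function(series, intercept = FALSE) {
  stopifnot(inherits(series, "dose_response_series"))
  a0 <- attr(series, "a0")
  a_inf <- attr(series, "a_inf")
  if (a0 == a_inf) stop("a0 equals a_inf: no dynamic range", call. = FALSE)
  use <- series$dose_Gy > 0
  d <- series$dose_Gy[use]
  at <- series$irradiated[use]
  # At must lie strictly between Ainf and A0 (open interval) for the log
  lo <- min(a0, a_inf); hi <- max(a0, a_inf)
  bad <- at <= lo | at >= hi
  if (any(bad)) {
    stop(sprintf("readout outside the open interval (A0, Ainf) at dose(s) %s",
                 paste(format(d[bad]), collapse = ", ")), call. = FALSE)
  }
  if (length(d) < 3) {
    stop("insufficient data: at least 3 non-zero dose points are required",
         call. = FALSE)
  }
  y <- log((a0 - a_inf) / (at - a_inf))
  fit <- if (intercept) stats::lm(y ~ d) else stats::lm(y ~ d + 0)
  sm <- suppressWarnings(summary(fit))  # noiseless data triggers the perfect-fit warning
  co <- sm$coefficients["d", ]
  structure(
    list(k_per_Gy = unname(co["Estimate"]),
         k_stderr = unname(co["Std. Error"]),
         r_squared = sm$r.squared,
         n_points = length(d),
         dose_range_Gy = range(d),
         intercept_used = intercept,
         model = fit),
    class = "activation_fit"
  )
}

#' @export
print.activation_fit <- function(x, ...) {
  cat(sprintf("<activation_fit> k = %.4g +/- %.2g /Gy (r2 = %.4f, n = %d, %g-%g Gy%s)\n",
              x$k_per_Gy, x$k_stderr, x$r_squared, x$n_points,
              x$dose_range_Gy[1], x$dose_range_Gy[2],
              if (x$intercept_used) ", with intercept" else ""))
  invisible(x)
}

#' G-value of trans-isomer production at a dose, with thermal correction
#'
#' Converts the trans-fraction increase at a given dose into a radiochemical
#' yield. With a paired control the thermally driven drift measured on the
#' dark plate at the matched timestamp is subtracted first
#' (`corrected_for_thermal = TRUE`); without one the raw increase is used
#' and flagged. The corrected fraction increase times the initial switch
#' concentration (uM), divided by the dose (Gy = J/kg at unit density),
#' gives umol/J, reported alongside molecules per 100 eV.
#'
#' @param series A [dose_response_series()] with `trans_fraction` readout.
#' @param initial_cis_uM Total switch concentration, uM (> 0). The series
#'   starts essentially all-cis, so this is the convertible pool.
#' @param dose_Gy The dose at which to evaluate (must be one of the series
#'   doses, > 0).
#' @param correct_thermal Subtract the paired-control drift; default `TRUE`.
#' @return A `g_value_result` with the yield as a [radiochemical_yield()],
#'   the flag `corrected_for_thermal`, and the inputs.
#' @export
fit_g_value <- function(series, initial_cis_uM, dose_Gy,
                        correct_thermal = TRUE) {
  stopifnot(inherits(series, "dose_response_series"))
  if (attr(series, "readout") != "trans_fraction") {
    stop("fit_g_value needs a trans_fraction series; convert absorbance first",
         call. = FALSE)
  }
  if (!is.numeric(dose_Gy) || dose_Gy <= 0) {
    stop("`dose_Gy` must be positive", call. = FALSE)
  }
  if (!is.numeric(initial_cis_uM) || initial_cis_uM <= 0) {
    stop("`initial_cis_uM` must be positive", call. = FALSE)
  }
  i <- match(dose_Gy, series$dose_Gy)
  if (is.na(i)) {
    stop(sprintf("dose %g Gy is not among the measured doses", dose_Gy),
         call. = FALSE)
  }
  d_irr <- series$irradiated[i] - series$irradiated[1]
  if (correct_thermal) {
    if (anyNA(series$control[c(1, i)])) {
      stop("paired control values are required for thermal correction",
           call. = FALSE)
    }
    d_ctrl <- series$control[i] - series$control[1]
  } else {
    d_ctrl <- 0
  }
  d_corr <- d_irr - d_ctrl
  if (d_corr < 0) {
    warning("corrected trans increment is negative; reporting the value as-is")
  }
  umol_per_J <- d_corr * initial_cis_uM / dose_Gy
  g <- if (umol_per_J >= 0) {
    radiochemical_yield(value_umol_per_J = umol_per_J, species = "trans-isomer")
  } else {
    # negative increments cannot go through the non-negative yield class
    structure(list(value_umol_per_J = umol_per_J,
                   value_per_100ev = umol_per_J / .UMOLJ_PER_100EV,
                   species = "trans-isomer"),
              class = "radiochemical_yield")
  }
  structure(
    list(g = g, corrected_for_thermal = correct_thermal,
         dose_Gy = dose_Gy, initial_cis_uM = initial_cis_uM,
         stderr = NA_real_),
    class = "g_value_result"
  )
}

#' @export
print.g_value_result <- function(x, ...) {
  cat(sprintf("<g_value_result> G = %.4g per 100 eV (%.4g umol/J) at %g Gy, %g uM%s\n",
              x$g$value_per_100ev, x$g$value_umol_per_J, x$dose_Gy,
              x$initial_cis_uM,
              if (x$corrected_for_thermal) ", thermal-corrected" else ""))
  invisible(x)
}

#' Coumarin assay data
#'
#' Fluorescence of 7-hydroxycoumarin (the single fluorescent product of
#' HO. scavenging by coumarin) versus dose, with the 7-OH-coumarin standard
#' curve and the coumarin-to-7-OH-coumarin conversion yield (default 3.1%).
#'
#' @param doses_Gy Doses in Gy.
#' @param fluorescence_au Background-corrected fluorescence, a.u.
#' @param standard_curve Numeric `c(slope, intercept)`: fluorescence =
#'   slope * concentration_uM + intercept; slope > 0.
#' @param conversion_yield Fraction of coumarin + HO. events yielding
#'   7-OH-coumarin, in (0, 1]; default 0.031.
#' @param gd_concentration_uM Gd3+ concentration of the run (metadata).
#' @return A `coumarin_assay` object.
#' @export
coumarin_assay <- function(doses_Gy, fluorescence_au,
                           standard_curve = c(slope = 1000, intercept = 0),
                           conversion_yield = 0.031,
                           gd_concentration_uM = 0) {
  if (length(doses_Gy) != length(fluorescence_au)) {
    stop("doses and fluorescence must have the same length", call. = FALSE)
  }
  if (standard_curve[1] <= 0) {
    stop("degenerate standard curve: slope must be positive", call. = FALSE)
  }
  if (conversion_yield <= 0 || conversion_yield > 1) {
    stop("`conversion_yield` must be in (0, 1]", call. = FALSE)
  }
  structure(
    list(doses_Gy = doses_Gy, fluorescence_au = fluorescence_au,
         standard_curve = c(slope = unname(standard_curve[1]),
                            intercept = unname(standard_curve[2])),
         conversion_yield = conversion_yield,
         gd_concentration_uM = gd_concentration_uM),
    class = "coumarin_assay"
  )
}

#' Hydroxyl-radical yield from a coumarin assay
#'
#' Fluorescence is converted to 7-OH-coumarin concentration through the
#' standard curve; the OLS slope of concentration versus dose is
#' G(7-OH-coumarin) in uM/Gy (numerically equal to umol/J at unit density),
#' and dividing by the conversion yield gives G(HO.).
#'
#' @param assay A [coumarin_assay()] with at least 3 dose points.
#' @return A [radiochemical_yield()] for species `"HO."`, with attributes
#'   `g_7ohc_umol_per_J`, `slope_stderr` and `r_squared`.
#' @export
fit_g_ho <- function(assay) {
  stopifnot(inherits(assay, "coumarin_assay"))
  if (length(unique(assay$doses_Gy)) < 3) {
    stop("insufficient data: at least 3 distinct doses are required",
         call. = FALSE)
  }
  conc <- (assay$fluorescence_au - assay$standard_curve["intercept"]) /
    assay$standard_curve["slope"]
  d <- assay$doses_Gy
  fit <- stats::lm(conc ~ d)
  sm <- suppressWarnings(summary(fit))  # noiseless data triggers the perfect-fit warning
  slope <- unname(stats::coef(fit)["d"])
  if (slope <= 0) {
    warning(sprintf("non-positive fitted 7-OH-coumarin slope (%.3g uM/Gy)",
                    slope))
    g <- structure(list(value_umol_per_J = slope / assay$conversion_yield,
                        value_per_100ev = slope / assay$conversion_yield /
                          .UMOLJ_PER_100EV,
                        species = "HO."),
                   class = "radiochemical_yield")
  } else {
    g <- radiochemical_yield(
      value_umol_per_J = slope / assay$conversion_yield, species = "HO.")
  }
  attr(g, "g_7ohc_umol_per_J") <- slope
  attr(g, "slope_stderr") <- sm$coefficients["d", "Std. Error"] /
    assay$conversion_yield
  attr(g, "r_squared") <- sm$r.squared
  g
}

#' Gd3+ enhancement profile from measured yields
#'
#' Given G(HO.) measured at several Gd3+ concentrations (including the
#' mandatory 0 baseline), computes the fractional enhancement
#' `G(c)/G(0) - 1` at each concentration and locates its maximum.
#'
#' @param g_by_gd Named numeric vector (names = concentrations in uM,
#'   values = yields in umol/J) or a data.frame with columns
#'   `gd_concentration_uM` and `g_ho_umol_per_J`. Must contain concentration
#'   0 with a positive yield.
#' @return A list with `profile` (data.frame of concentration and
#'   enhancement), `max_enhancement` and `argmax_concentration_uM`.
#' @examples
#' enhancement_profile(c(`0` = 0.280, `500` = 0.336))  # max 0.20 at 500 uM
#' @export
enhancement_profile <- function(g_by_gd) {
  if (is.data.frame(g_by_gd)) {
    conc <- g_by_gd$gd_concentration_uM
    g <- g_by_gd$g_ho_umol_per_J
  } else {
    conc <- as.numeric(names(g_by_gd))
    g <- as.numeric(g_by_gd)
  }
  i0 <- which(conc == 0)
  if (length(i0) != 1 || g[i0] <= 0) {
    stop("a positive baseline yield at concentration 0 is required",
         call. = FALSE)
  }
  enh <- g / g[i0] - 1
  keep <- conc > 0
  profile <- data.frame(gd_concentration_uM = conc[keep],
                        enhancement = enh[keep])
  imax <- which.max(enh)
  list(profile = profile,
       max_enhancement = enh[imax],
       argmax_concentration_uM = conc[imax])
}

#' Thermal relaxation half-life from a time course
#'
#' Log-linearisation of the first-order dark relaxation: OLS of
#' `ln(1 - trans)` on time gives slope `-ln2 / t_half`. Saturated
#' (`trans >= 1`) points are filtered with a warning; at least 4 usable
#' points are required. Exact recovery on noiseless data.
#'
#' @param timecourse Data.frame with columns `time_h` and `trans_fraction`.
#' @return A list with `half_life_h`, `stderr_h`, `r_squared`, `n_points`.
#' @export
fit_thermal_half_life <- function(timecourse) {
  stopifnot(is.data.frame(timecourse),
            all(c("time_h", "trans_fraction") %in% names(timecourse)))
  t <- timecourse$time_h
  tr <- timecourse$trans_fraction
  ok <- is.finite(tr) & tr < 1
  if (any(!ok)) {
    warning(sprintf("%d saturated or non-finite point(s) filtered", sum(!ok)))
  }
  t <- t[ok]; tr <- tr[ok]
  if (length(t) < 4 || length(unique(t)) < 2) {
    stop("insufficient data: at least 4 usable time points are required",
         call. = FALSE)
  }
  y <- log(1 - tr)
  fit <- stats::lm(y ~ t)
  sm <- suppressWarnings(summary(fit))  # noiseless data triggers the perfect-fit warning
  slope <- unname(stats::coef(fit)["t"])
  if (slope >= 0) {
    stop("insufficient data: trans fraction does not increase over the course",
         call. = FALSE)
  }
  se <- sm$coefficients["t", "Std. Error"]
  hl <- log(2) / abs(slope)
  list(half_life_h = hl,
       stderr_h = hl * se / abs(slope),  # delta method
       r_squared = sm$r.squared,
       n_points = length(t))
}

#' Fit the logarithmic dose-efficiency model
#'
#' OLS of the per-concentration G-value slope `Y` on `ln(dose)`:
#' `Y = a ln(D) + b`. Recovers generating coefficients exactly on noiseless
#' data.
#'
#' @param g_per_conc_by_dose Named numeric vector (names = doses in Gy,
#'   values = Y in G-value per uM) or a data.frame with columns `dose_Gy`
#'   and `g_per_uM`. At least 3 strictly positive doses.
#' @return A list with `a`, `b`, `r_squared`, `a_stderr`, `b_stderr`.
#' @export
fit_efficiency_model <- function(g_per_conc_by_dose) {
  if (is.data.frame(g_per_conc_by_dose)) {
    d <- g_per_conc_by_dose$dose_Gy
    y <- g_per_conc_by_dose$g_per_uM
  } else {
    d <- as.numeric(names(g_per_conc_by_dose))
    y <- as.numeric(g_per_conc_by_dose)
  }
  if (any(d <= 0)) {
    stop("all doses must be strictly positive", call. = FALSE)
  }
  if (length(unique(d)) < 3) {
    stop("insufficient data: at least 3 distinct doses are required",
         call. = FALSE)
  }
  ld <- log(d)
  fit <- stats::lm(y ~ ld)
  sm <- suppressWarnings(summary(fit))  # noiseless data triggers the perfect-fit warning
  list(a = unname(stats::coef(fit)["ld"]),
       b = unname(stats::coef(fit)["(Intercept)"]),
       r_squared = sm$r.squared,
       a_stderr = sm$coefficients["ld", "Std. Error"],
       b_stderr = sm$coefficients["(Intercept)", "Std. Error"])
}
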
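# Canonical unit system: concentrations in uM, doses in Gy, times in hours.
# Conversions happen here and only here.

# CODATA 2018 exact values
.ELEMENTARY_CHARGE_J_PER_EV <- 1.602176634e-19
.AVOGADRO_PER_MOL <- 6.02214076e23

# 1 (molecule / 100 eV) = .UMOLJ_PER_100EV umol/J  (~0.1036427)
.UMOLJ_PER_100EV <- 1e6 / (100 * .ELEMENTARY_CHARGE_J_PER_EV * .AVOGADRO_PER_MOL)

.check_nonneg <- function(x, what) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0)) {
    stop(sprintf("`%s` must be finite and non-negative (got %s)",
                 what, paste(format(x), collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}

#' Convert a radiochemical yield from molecules per 100 eV to umol/J
#'
#' The G-value of a radiolytic species counts molecules produced (or consumed)
#' per 100 eV of absorbed energy; the SI-style equivalent is micromoles per
#' joule. The two differ by the exact factor
#' \eqn{10^6 / (100 \, e \, N_A) \approx 0.1036}, using CODATA values of the
#' elementary charge and the Avogadro constant.
#'
#' @param g Yield in molecules per 100 eV (non-negative, finite).
#' @return Yield in umol/J.
#' @examples
#' g_per_100ev_to_umol_per_J(81)    # ~8.4 umol/J
#' umol_per_J_to_g_per_100ev(0.28)  # ~2.70 per 100 eV
#' @seealso [umol_per_J_to_g_per_100ev()], [radiochemical_yield()]
#' @export
g_per_100ev_to_umol_per_J <- function(g) {
  .check_nonneg(g, "g")
  g * .UMOLJ_PER_100EV
}

#' Convert a radiochemical yield from umol/J to molecules per 100 eV
#'
#' Inverse of [g_per_100ev_to_umol_per_J()]; the round trip is exact to
#' floating-point precision.
#'
#' @param x Yield in umol/J (non-negative, finite).
#' @return Yield in molecules per 100 eV.
#' @export
umol_per_J_to_g_per_100ev <- function(x) {
  .check_nonneg(x, "x")
  x / .UMOLJ_PER_100EV
}

#' Radiochemical yield carrying both unit representations
#'
#' A small value class holding a G-value simultaneously in umol/J and in
#' molecules per 100 eV, kept consistent by construction. Exactly one of the
#' two representations must be supplied.
#'
#' @param value_umol_per_J Yield in umol/J.
#' @param value_per_100ev Yield in molecules per 100 eV.
#' @param species Label of the species the yield refers to, e.g. `"HO."` or
#'   `"trans-isomer"`.
#' @return An object of class `radiochemical_yield` with fields
#'   `value_umol_per_J`, `value_per_100ev` and `species`.
#' @examples
#' radiochemical_yield(value_per_100ev = 81, species = "trans-isomer")
#' @export
radiochemical_yield <- function(value_umol_per_J = NULL, value_per_100ev = NULL,
                                species = "HO.") {
  if (is.null(value_umol_per_J) == is.null(value_per_100ev)) {
    stop("supply exactly one of `value_umol_per_J` or `value_per_100ev`",
         call. = FALSE)
  }
  if (is.null(value_umol_per_J)) {
    value_umol_per_J <- g_per_100ev_to_umol_per_J(value_per_100ev)
  } else {
    .check_nonneg(value_umol_per_J, "value_umol_per_J")
    value_per_100ev <- umol_per_J_to_g_per_100ev(value_umol_per_J)
  }
  structure(
    list(value_umol_per_J = value_umol_per_J,
         value_per_100ev = value_per_100ev,
         species = species),
    class = "radiochemical_yield"
  )
}

#' @export
print.radiochemical_yield <- function(x, ...) {
  cat(sprintf("G(%s) = %.4g umol/J  (%.4g per 100 eV)\n",
              x$species, x$value_umol_per_J, x$value_per_100ev))
  invisible(x)
}

#' Concentration of a radiolytic species produced by a dose
#'
#' With dose in gray (J/kg) and a yield in umol/J, the amount of species
#' produced per litre of solution is `yield * dose * density`, in umol/L = uM.
#' Exactly linear in both dose and yield.
#'
#' @param dose_Gy Absorbed dose in Gy (non-negative).
#' @param yield_umol_per_J Radiochemical yield in umol/J, or a
#'   [radiochemical_yield()] object.
#' @param density_kg_per_L Solution density, default 1.0 (dilute aqueous).
#' @return Species concentration in uM.
#' @examples
#' species_concentration_from_dose(2, 0.28)  # 0.56 uM HO. from 2 Gy in water
#' @export
species_concentration_from_dose <- function(dose_Gy, yield_umol_per_J,
                                            density_kg_per_L = 1.0) {
  if (inherits(yield_umol_per_J, "radiochemical_yield")) {
    yield_umol_per_J <- yield_umol_per_J$value_umol_per_J
  }
  .check_nonneg(dose_Gy, "dose_Gy")
  .check_nonneg(yield_umol_per_J, "yield_umol_per_J")
  if (!is.numeric(density_kg_per_L) || density_kg_per_L <= 0) {
    stop("`density_kg_per_L` must be positive", call. = FALSE)
  }
  yield_umol_per_J * dose_Gy * density_kg_per_L
}

#' Equivalent dose across solution conditions
#'
#' Maps a dose delivered under one set of solution conditions onto the dose
#' that would generate the same amount of hydroxyl radicals under another set
#' of conditions: `dose * G_eff(from) / G_eff(to)`. This is the construction
#' behind "eq" dose labels for N2O-saturated runs: 5 Gy under N2O (doubled
#' G(HO.)) is water-equivalent to 10 Gy.
#'
#' @param dose_Gy Dose delivered under `conditions_from`, in Gy.
#' @param conditions_from,conditions_to [solution_conditions()] objects.
#' @param source A [radiation_source()] (or preset name, see [ir_source()]).
#' @return The equivalent dose in Gy under `conditions_to`.
#' @examples
#' equivalent_dose(5, solution_conditions(gas = "N2O"),
#'                 solution_conditions(), ir_source("GR"))  # 10 Gy
#' @export
equivalent_dose <- function(dose_Gy, conditions_from, conditions_to, source) {
  .check_nonneg(dose_Gy, "dose_Gy")
  g_from <- effective_g_ho(source, conditions_from)$value_umol_per_J
  g_to <- effective_g_ho(source, conditions_to)$value_umol_per_J
  if (g_to <= 0) {
    stop("effective G(HO.) is zero in the target conditions; ",
         "the equivalent dose is undefined", call. = FALSE)
  }
  if (g_from <= 0) {
    stop("effective G(HO.) is zero in the source conditions", call. = FALSE)
  }
  dose_Gy * g_from / g_to
}

#' Convert a yield value between its two unit representations
#'
#' Convenience wrapper used by the command-line `convert` subcommand.
#'
#' @param value Numeric yield value.
#' @param from Unit of `value`: `"per_100ev"` or `"umol_per_J"`.
#' @return The value in the other unit.
#' @export
convert_yield <- function(value, from = c("per_100ev", "umol_per_J")) {
  from <- match.arg(from)
  if (from == "per_100ev") g_per_100ev_to_umol_per_J(value)
  else umol_per_J_to_g_per_100ev(value)
}
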
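#' Equilibrium carbon-isotope fractionation coefficients
#'
#' Temperature-dependent equilibrium fractionations among gaseous CO2,
#' dissolved CO2, bicarbonate and calcite, each expressed as
#' `eps(T) = A / T_K + B` in permil with `T_K` in kelvin. The default set
#' is the classical seawater equilibria (dissolved CO2 vs gas,
#' bicarbonate vs gas, calcite vs bicarbonate). The coefficients live in
#' this one block so an alternative edition can be swapped in without
#' touching any logic.
#'
#' @return A named list of `c(A, B)` pairs.
#' @export
mook_coefficients <- function() {
  list(
    aq_gas = c(A = -373, B = 0.19),        # CO2(aq) vs CO2(g)
    bicarb_gas = c(A = 9483, B = -23.89),  # HCO3- vs CO2(g)
    calcite_bicarb = c(A = -4232, B = 15.10)  # CaCO3 vs HCO3-
  )
}

eps_at_T <- function(coef, temperature_C) {
  coef[["A"]] / (temperature_C + 273.15) + coef[["B"]]
}

## exact (ratio-form) application of a permil fractionation to a delta
apply_eps <- function(d13c, eps) {
  (1 + eps / 1000) * (1000 + d13c) - 1000
}

#' Carbonate-organic carbon isotope separation (epsilon_TOC)
#'
#' The isotopic separation between coexisting carbonate and organic
#' carbon, in the exact ratio form
#' `1000 * ((1000 + d13c_carb) / (1000 + d13c_org) - 1)`, which reduces
#' to the simple difference `d13c_carb - d13c_org` to first order.
#'
#' @param d13c_carb,d13c_org delta-13C of carbonate and organic carbon
#'   (permil vs VPDB).
#' @return epsilon_TOC in permil.
#' @examples
#' epsilon_toc(2, -27)  # 29.80
#' @export
epsilon_toc <- function(d13c_carb, d13c_org) {
  if (any(d13c_org <= -1000, na.rm = TRUE)) {
    abort("`d13c_org` at or below -1000 permil is outside the delta scale")
  }
  1000 * ((1000 + d13c_carb) / (1000 + d13c_org) - 1)
}

#' Carbonate vs dissolved-CO2 isotope separation (Delta_CARB)
#'
#' The isotope difference between carbonate minerals and dissolved CO2.
#' The delta-13C of dissolved CO2 is derived from the atmospheric value
#' via the temperature-dependent gas/aqueous equilibrium fractionation
#' (coefficient block [mook_coefficients()]), and
#' `Delta_CARB = d13c_carb - d13C_CO2(aq)`. At marine temperatures this
#' is of order +8 to +10 permil. Temperatures outside (-5, 60) degrees C
#' trigger an extrapolation warning.
#'
#' @param temperature Water temperature in degrees C (vectorized).
#' @param d13c_atm delta-13C of atmospheric CO2 (permil); default -5, the
#'   pre-industrial value, held constant through time.
#' @param d13c_carb delta-13C of carbonate (permil vs VPDB).
#' @param coefficients Coefficient block; see [mook_coefficients()].
#' @return Delta_CARB in permil.
#' @export
delta_carb <- function(temperature, d13c_atm = -5, d13c_carb,
                       coefficients = mook_coefficients()) {
  out_of_range <- !is.na(temperature) & (temperature <= -5 | temperature >= 60)
  if (any(out_of_range)) {
    warn("temperature outside (-5, 60) C: fractionation expressions extrapolated")
  }
  eps_ag <- eps_at_T(coefficients$aq_gas, temperature)
  d13c_co2aq <- apply_eps(d13c_atm, eps_ag)
  d13c_carb - d13c_co2aq
}

#' Photosynthetic fractionation proxy epsilon_P - Delta_2
#'
#' Computes the carbon-demand proxy
#' `ep_minus_delta2 = epsilon_TOC - Delta_CARB` from paired organic and
#' carbonate delta-13C plus a water temperature. High values indicate
#' large photosynthetic fractionation (abundant CO2 relative to demand);
#' values fall when carbon demand is high relative to available CO2.
#' Delta_2 itself (the secondary-biology offset, typically 1.5 permil) is
#' *not* subtracted; it is attached as metadata (`attr(., "delta2")`) for
#' anyone deriving epsilon_P proper.
#'
#' @param data Data frame with columns `d13c_org`, `d13c_carb` and
#'   `temperature` (degrees C).
#' @param d13c_atm Atmospheric delta-13C (permil), default -5.
#' @param coefficients See [mook_coefficients()].
#' @return The input as a tibble with added columns `eps_toc`,
#'   `delta_carb` and `ep_minus_delta2`.
#' @examples
#' ep_minus_delta2(data.frame(d13c_org = -27, d13c_carb = 2, temperature = 25))
#' @export
ep_minus_delta2 <- function(data, d13c_atm = -5,
                            coefficients = mook_coefficients()) {
  need <- c("d13c_org", "d13c_carb")
  miss <- setdiff(need, names(data))
  if (length(miss) > 0) {
    abort(paste0("`data` is missing column(s): ", paste(miss, collapse = ", ")))
  }
  if (!"temperature" %in% names(data)) {
    abort(paste(
      "`data` has no `temperature` column: Delta_CARB needs a water",
      "temperature; supply an age->temperature curve (see",
      "carbon_systematics())."
    ))
  }
  out <- as_tibble(data) |>
    mutate(
      eps_toc = epsilon_toc(.data$d13c_carb, .data$d13c_org),
      delta_carb = delta_carb(.data$temperature, d13c_atm, .data$d13c_carb,
                              coefficients),
      ep_minus_delta2 = .data$eps_toc - .data$delta_carb
    )
  attr(out, "delta2") <- 1.5
  out
}

#' Carbon systematics for a dated record with an external temperature curve
#'
#' Joins an age -> temperature table onto a carbon-isotope record by
#' linear interpolation in age and computes epsilon_TOC, Delta_CARB and
#' epsilon_P - Delta_2 for every sample (see [ep_minus_delta2()]).
#'
#' @param records Data frame with columns `age`, `d13c_org`, `d13c_carb`.
#' @param temps Data frame with columns `age` (Ma) and `temperature`
#'   (degrees C); interpolated linearly, clamped at its ends.
#' @param ... Passed on to [ep_minus_delta2()].
#' @return Tibble with a `temperature` column and the three derived
#'   columns.
#' @export
carbon_systematics <- function(records, temps, ...) {
  if (!all(c("age", "temperature") %in% names(temps))) {
    abort("`temps` must have columns `age` and `temperature`")
  }
  if (!"age" %in% names(records)) abort("`records` must have an `age` column")
  tt <- approx(temps$age, temps$temperature, xout = records$age,
               rule = 2, ties = mean)
  records |>
    as_tibble() |>
    mutate(temperature = tt$y) |>
    ep_minus_delta2(...)
}
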
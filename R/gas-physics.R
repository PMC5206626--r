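# Physical-chemistry kernel: Schmidt numbers, k normalisation, Henry's-law
# equilibria, diffusive flux and CO2-equivalents.
#
# Unit policy (applies package-wide): dissolved concentrations in uM
# (= mmol m^-3), gas transfer velocities in m d^-1, fluxes in mmol m^-2 d^-1.
# Conversions happen only at I/O boundaries.

# Freshwater fourth-order Schmidt polynomials Sc(T) = a0 + a1*T + ... (T in
# degC) for CO2 and CH4; chosen so Sc(CO2, 20 degC) rounds to 600, the
# reference value behind k600. Propane has no polynomial: Sc = nu(T)/D(T)
# with an Arrhenius diffusivity fit anchored to the classic
# sparingly-soluble-gas measurements (see gas_spec()).
.gas_table <- list(
  CH4 = list(
    molar_mass = 16.04,
    schmidt_coeffs = c(1909.4, -120.78, 4.1555, -0.080578, 0.00065777),
    henry = list(type = "bunsen", coeffs = c(-67.1962, 99.1624, 27.9015))
  ),
  CO2 = list(
    molar_mass = 44.01,
    schmidt_coeffs = c(1923.6, -125.06, 4.3773, -0.085681, 0.00070284),
    henry = list(type = "molar", coeffs = c(-58.0931, 90.5069, 22.2940))
  ),
  C3H8 = list(
    molar_mass = 44.10,
    schmidt_coeffs = NULL,
    diffusion = list(pre_exp_cm2_s = 1.087e-2, e_a_J_mol = 16981),
    henry = list(type = "vant_hoff", kh_25 = 1.4e-3, d_ln_kh = 2700)
  )
)

.sc_temp_range <- c(0, 35)

#' Gas specification
#'
#' Bundle of per-gas physical constants: molar mass, the freshwater
#' Schmidt-number parameterisation and the Henry solubility function used for
#' atmospheric-equilibrium concentrations. CH4 and CO2 carry fourth-order
#' freshwater Schmidt polynomials in temperature; propane (C3H8, the volatile
#' tracer used for whole-stream injections) has its Schmidt number computed as
#' kinematic viscosity over an Arrhenius-type diffusivity fit, whose
#' parameters can be overridden here if an alternative diffusivity
#' parameterisation is preferred.
#'
#' @param name One of `"CH4"`, `"CO2"`, `"C3H8"`.
#' @param diffusion For `"C3H8"` only: optional list with elements
#'   `pre_exp_cm2_s` (Arrhenius pre-exponential, cm^2 s^-1) and `e_a_J_mol`
#'   (activation energy, J mol^-1) replacing the built-in fit.
#' @return An object of class `gas_spec`.
#' @examples
#' gas_spec("CO2")
#' schmidt_number(gas_spec("CH4"), 20)
#' @export
gas_spec <- function(name = c("CH4", "CO2", "C3H8"), diffusion = NULL) {
  name <- match.arg(name)
  spec <- .gas_table[[name]]
  if (!is.null(diffusion)) {
    if (name != "C3H8") {
      stop("diffusion overrides are only meaningful for C3H8", call. = FALSE)
    }
    stopifnot(is.list(diffusion),
              all(c("pre_exp_cm2_s", "e_a_J_mol") %in% names(diffusion)))
    spec$diffusion <- diffusion
  }
  structure(c(list(name = name), spec), class = "gas_spec")
}

#' @export
print.gas_spec <- function(x, ...) {
  cat("<gas_spec>", x$name, "\n")
  cat("  molar mass:", x$molar_mass, "g mol^-1\n")
  if (is.null(x$schmidt_coeffs)) {
    cat("  Schmidt: nu(T)/D(T), Arrhenius D fit (pre-exp",
        format(x$diffusion$pre_exp_cm2_s), "cm2 s^-1, Ea",
        format(x$diffusion$e_a_J_mol), "J mol^-1)\n")
  } else {
    cat("  Schmidt: freshwater polynomial, Sc(20 degC) =",
        round(schmidt_number(x, 20), 1), "\n")
  }
  cat("  KH(10 degC):", signif(henry_constant(x, 10), 4), "mol L^-1 atm^-1\n")
  invisible(x)
}

.as_gas_spec <- function(gas) {
  if (inherits(gas, "gas_spec")) gas else gas_spec(gas)
}

#' Pure-water viscosity and density
#'
#' Helper correlations for the propane Schmidt number: dynamic viscosity from
#' the Vogel equation and density from the standard polynomial approximation,
#' combined into kinematic viscosity.
#'
#' @param temp_c Water temperature (degC).
#' @return `water_kinematic_viscosity()`: kinematic viscosity in cm^2 s^-1.
#' @export
water_kinematic_viscosity <- function(temp_c) {
  t_k <- temp_c + 273.15
  mu_mpas <- exp(-3.7188 + 578.919 / (t_k - 137.546))          # mPa s
  rho <- 1 - (temp_c + 288.9414) * (temp_c - 3.9863)^2 /
    (508929.2 * (temp_c + 68.12963))                           # g cm^-3
  mu_mpas * 0.01 / rho                                         # cm^2 s^-1
}

#' Schmidt number of a gas in freshwater
#'
#' Temperature-dependent Schmidt number Sc = nu/D used to normalise gas
#' transfer velocities across gases and temperatures. CH4 and CO2 use the
#' freshwater polynomial fits stored on the gas spec; propane uses the
#' kinematic viscosity of pure water divided by an Arrhenius diffusivity fit.
#'
#' @param gas A [gas_spec()] or gas name.
#' @param temp_c Water temperature (degC), within 0-35.
#' @return Dimensionless Schmidt number (vectorised over `temp_c`).
#' @examples
#' round(schmidt_number("CO2", 20)) # 600 by construction of k600
#' @export
schmidt_number <- function(gas, temp_c) {
  gas <- .as_gas_spec(gas)
  if (any(temp_c < .sc_temp_range[1] | temp_c > .sc_temp_range[2])) {
    stop(sprintf(
      "Schmidt number for %s is parameterised for %g-%g degC (got %s)",
      gas$name, .sc_temp_range[1], .sc_temp_range[2],
      paste(signif(temp_c[temp_c < .sc_temp_range[1] |
                            temp_c > .sc_temp_range[2]], 4), collapse = ", ")),
      call. = FALSE)
  }
  if (!is.null(gas$schmidt_coeffs)) {
    a <- gas$schmidt_coeffs
    a[1] + a[2] * temp_c + a[3] * temp_c^2 + a[4] * temp_c^3 + a[5] * temp_c^4
  } else {
    t_k <- temp_c + 273.15
    d_cm2_s <- gas$diffusion$pre_exp_cm2_s *
      exp(-gas$diffusion$e_a_J_mol / (8.314462 * t_k))
    water_kinematic_viscosity(temp_c) / d_cm2_s
  }
}

#' Normalise a gas transfer velocity to k600
#'
#' Converts a measured gas- and temperature-specific transfer velocity to the
#' standard k600 (the k of a gas with Schmidt number 600, i.e. CO2 at 20 degC
#' in freshwater) with the n = -1/2 Schmidt exponent:
#' k600 = k * (600/Sc)^(-1/2).
#'
#' @param k Gas transfer velocity (m d^-1), >= 0.
#' @param sc Schmidt number of the measured gas at the measurement
#'   temperature, > 0.
#' @return k600 (m d^-1).
#' @seealso [k_gas_from_k600()] for the exact inverse.
#' @export
k600_from_k <- function(k, sc) {
  if (any(sc <= 0)) stop("Schmidt number must be positive", call. = FALSE)
  if (any(k < 0)) stop("k must be non-negative", call. = FALSE)
  k * (600 / sc)^(-1 / 2)
}

#' Gas-specific transfer velocity from k600
#'
#' Inverse of [k600_from_k()]: k_gas = k600 * (Sc_gas/600)^(-1/2), used to
#' obtain k for CH4 or CO2 at the in-situ water temperature from a modelled or
#' measured k600.
#'
#' @param k600 Normalised gas transfer velocity (m d^-1), >= 0.
#' @param sc_gas Schmidt number of the target gas at the target temperature.
#' @return k for the target gas (m d^-1).
#' @export
k_gas_from_k600 <- function(k600, sc_gas) {
  if (any(sc_gas <= 0)) stop("Schmidt number must be positive", call. = FALSE)
  if (any(k600 < 0)) stop("k600 must be non-negative", call. = FALSE)
  k600 * (sc_gas / 600)^(-1 / 2)
}

#' Henry solubility constant in freshwater
#'
#' KH(T) in mol L^-1 atm^-1. CO2 uses the freshwater molar solubility fit
#' ln KH = a1 + a2*(100/T) + a3*ln(T/100); CH4 uses the corresponding
#' freshwater Bunsen-coefficient fit divided by the molar volume
#' 22.414 L mol^-1; propane uses a van't Hoff extrapolation from 25 degC.
#' All are positive and strictly decreasing with temperature over 0-30 degC.
#'
#' @inheritParams schmidt_number
#' @return KH in mol L^-1 atm^-1 (vectorised over `temp_c`).
#' @export
henry_constant <- function(gas, temp_c) {
  gas <- .as_gas_spec(gas)
  if (any(temp_c < .sc_temp_range[1] | temp_c > .sc_temp_range[2])) {
    stop(sprintf("Henry constant for %s is parameterised for %g-%g degC",
                 gas$name, .sc_temp_range[1], .sc_temp_range[2]),
         call. = FALSE)
  }
  t_k <- temp_c + 273.15
  h <- gas$henry
  switch(h$type,
    molar = exp(h$coeffs[1] + h$coeffs[2] * (100 / t_k) +
                  h$coeffs[3] * log(t_k / 100)),
    bunsen = exp(h$coeffs[1] + h$coeffs[2] * (100 / t_k) +
                   h$coeffs[3] * log(t_k / 100)) / 22.414,
    vant_hoff = h$kh_25 * exp(h$d_ln_kh * (1 / t_k - 1 / 298.15)),
    stop("unknown Henry parameterisation", call. = FALSE)
  )
}

#' Atmospheric-equilibrium dissolved concentration
#'
#' Dissolved gas concentration in equilibrium with a given atmospheric mixing
#' ratio by Henry's law: C_eq = KH(T) * x * P, returned in uM. With KH in
#' mol L^-1 atm^-1 and the mixing ratio in ppm, the ppm-to-atm factor (1e-6)
#' and the mol-to-umol factor (1e6) cancel, so C_eq(uM) = KH * ppm * P.
#'
#' @param atm_ppm Atmospheric mixing ratio (ppm), >= 0.
#' @inheritParams schmidt_number
#' @param pressure Total pressure (atm), default 1.
#' @return Equilibrium concentration (uM).
#' @examples
#' equilibrium_concentration(2.0, 10, "CH4")   # ~0.004 uM
#' equilibrium_concentration(405, 8, "CO2")    # ~23 uM
#' @export
equilibrium_concentration <- function(atm_ppm, temp_c, gas, pressure = 1) {
  if (any(atm_ppm < 0)) stop("mixing ratio must be >= 0", call. = FALSE)
  if (any(pressure <= 0)) stop("pressure must be positive", call. = FALSE)
  henry_constant(gas, temp_c) * atm_ppm * pressure
}

#' Diffusive air-water gas flux
#'
#' F = k_gas * (C_aq - C_eq). With k in m d^-1 and concentrations in uM
#' (= mmol m^-3) the result is in mmol m^-2 d^-1 with no further unit
#' factors. Negative values indicate undersaturation (uptake).
#'
#' @param k_gas Gas-specific transfer velocity (m d^-1), >= 0.
#' @param c_aq Dissolved concentration (uM).
#' @param c_eq Atmospheric-equilibrium concentration (uM).
#' @return Flux to the atmosphere (mmol m^-2 d^-1).
#' @export
diffusive_flux <- function(k_gas, c_aq, c_eq) {
  if (any(k_gas < 0)) stop("k must be non-negative", call. = FALSE)
  k_gas * (c_aq - c_eq)
}

#' CO2-equivalent total of CH4 and CO2 emissions
#'
#' Converts a CH4 mass emission (kg yr^-1) to CO2-equivalents with a global
#' warming potential (default 28, 100-year horizon) and adds the CO2 emission
#' (Mg yr^-1): total = co2 + ch4 * gwp / 1000. The CH4 share is the
#' percentage of the total contributed by CH4 (0 when the total is 0).
#'
#' @param ch4_kg_yr CH4 emission (kg yr^-1), >= 0.
#' @param co2_mg_yr CO2 emission (Mg yr^-1), >= 0.
#' @param gwp Global warming potential of CH4 (mass basis), default 28.
#' @return List with `total_mg_co2e_yr` and `ch4_share_pct`.
#' @examples
#' co2_equivalents(89.5, 32.9) # 35.4 Mg CO2-eq yr^-1, CH4 share ~7 %
#' @export
co2_equivalents <- function(ch4_kg_yr, co2_mg_yr, gwp = 28) {
  if (any(ch4_kg_yr < 0) || any(co2_mg_yr < 0)) {
    stop("emission masses must be non-negative", call. = FALSE)
  }
  ch4_co2e <- ch4_kg_yr * gwp / 1000
  total <- co2_mg_yr + ch4_co2e
  share <- ifelse(total > 0, 100 * ch4_co2e / total, 0)
  list(total_mg_co2e_yr = total, ch4_share_pct = share)
}
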
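# Per-reach daily flux integration and catchment aggregation: combines
# modelled k600, water temperature and reconstructed concentrations into
# diffusive fluxes, then into annual network totals, CO2-equivalents,
# uncertainty bounds and hot-spot / hot-moment category summaries.

#' Per-reach-day diffusive emission
#'
#' For one gas: converts k600 to the gas- and temperature-specific k,
#' computes the Henry's-law equilibrium concentration for the atmospheric
#' mixing ratio, the diffusive flux F = k_gas (C_aq - C_eq), and the areal
#' mass emission mass = F * area * M / 1e6 (kg d^-1, M in g mol^-1).
#'
#' @param k600_md Normalised gas transfer velocity (m d^-1).
#' @param water_temp_c Water temperature (degC).
#' @param conc_um Dissolved concentration (uM).
#' @param atm_ppm Atmospheric mixing ratio (ppm).
#' @param gas A [gas_spec()] or gas name ("CH4" or "CO2").
#' @param area_m2 Reach surface area (m^2).
#' @return Data frame with `k_gas_md`, `c_eq_um`, `flux_mmol_m2_d`,
#'   `mass_kg_d`.
#' @export
reach_day_emission <- function(k600_md, water_temp_c, conc_um, atm_ppm,
                               gas, area_m2) {
  gas <- .as_gas_spec(gas)
  sc <- schmidt_number(gas, water_temp_c)
  k_gas <- k_gas_from_k600(k600_md, sc)
  c_eq <- equilibrium_concentration(atm_ppm, water_temp_c, gas)
  flux <- diffusive_flux(k_gas, conc_um, c_eq)
  data.frame(
    k_gas_md = k_gas,
    c_eq_um = c_eq,
    flux_mmol_m2_d = flux,
    mass_kg_d = flux * area_m2 * gas$molar_mass / 1e6
  )
}

#' Symmetric uncertainty bounds around a mean
#'
#' (low, high) = mean * (1 -+ pct/100), the convention used to propagate the
#' spatial-interpolation uncertainty (e.g. +-60 % for CH4, +-25 % for CO2)
#' onto mean fluxes and totals.
#'
#' @param mean_value Central value.
#' @param pct Relative uncertainty in percent.
#' @return Named vector `c(low, high)` (or two-column matrix for vector
#'   input).
#' @export
uncertainty_bounds <- function(mean_value, pct) {
  if (any(pct < 0)) stop("uncertainty percentage must be >= 0", call. = FALSE)
  low <- mean_value * (1 - pct / 100)
  high <- mean_value * (1 + pct / 100)
  if (length(mean_value) == 1 && length(pct) == 1) {
    c(low = low, high = high)
  } else {
    cbind(low = low, high = high)
  }
}

.discharge_bin_labels <- c("<1", "1-2", "2-3", "3-4", ">4")

#' Discharge-ratio category of a reach-day
#'
#' Ratio of the day's reach discharge to that reach's study-period mean
#' discharge, binned into the five hot-moment categories. The first bin
#' contains all ratios <= 1 (most days sit at or below the mean); the
#' remaining bins are lower-inclusive: \[2,3) is "2-3", and so on.
#'
#' @param q Reach discharge on the day (L s^-1).
#' @param mean_q Study-period mean discharge of the reach (L s^-1), > 0.
#' @return Factor with levels `<1`, `1-2`, `2-3`, `3-4`, `>4`.
#' @export
discharge_ratio_bin <- function(q, mean_q) {
  if (any(mean_q <= 0)) stop("mean discharge must be positive", call. = FALSE)
  r <- q / mean_q
  lab <- ifelse(r <= 1, "<1",
         ifelse(r < 2, "1-2",
         ifelse(r < 3, "2-3",
         ifelse(r < 4, "3-4", ">4"))))
  factor(lab, levels = .discharge_bin_labels)
}

#' Hot-spot / hot-moment category ratio table
#'
#' Ratio of the mean areal emission (and mean k600) in each category to the
#' overall mean, plus the category's share of stream area (slope categories)
#' or of reach-days (discharge-ratio categories). Ratios above 1 mark
#' disproportionately emitting categories; sampling only in categories with
#' ratios below 1 underestimates the network total.
#'
#' @param states Reach-day table with columns `reach_id`, `flux_CH4`,
#'   `flux_CO2`, `k600_md`, `discharge_Ls` and logical `excluded`; excluded
#'   (ice) days are dropped.
#' @param reaches Reach table from [discretize()] (for areas and slope
#'   categories).
#' @param by `"slope_category"` or `"discharge_bin"`.
#' @return Data frame with the category, its percent share, and the
#'   CH4-emission, CO2-emission and k600 ratios to the overall mean.
#' @export
category_ratios <- function(states, reaches,
                            by = c("slope_category", "discharge_bin")) {
  by <- match.arg(by)
  st <- states[!states$excluded, , drop = FALSE]
  if (by == "slope_category") {
    st$cat <- reaches$slope_category[match(st$reach_id, reaches$reach_id)]
    area <- tapply(reaches$area_m2, reaches$slope_category, sum,
                   default = 0)
    share <- 100 * area / sum(reaches$area_m2)
    levels_ <- levels(reaches$slope_category)
  } else {
    mean_q <- tapply(st$discharge_Ls, st$reach_id, mean)
    st$cat <- discharge_ratio_bin(st$discharge_Ls,
                                  mean_q[st$reach_id])
    share <- 100 * table(st$cat) / nrow(st)
    levels_ <- .discharge_bin_labels
  }
  ratio_of <- function(x) {
    overall <- mean(x, na.rm = TRUE)
    as.numeric(tapply(x, st$cat, mean, na.rm = TRUE)[levels_] / overall)
  }
  data.frame(
    category = levels_,
    percent = as.numeric(share[levels_]),
    ch4_emission_ratio = ratio_of(st$flux_CH4),
    co2_emission_ratio = ratio_of(st$flux_CO2),
    k_ratio = ratio_of(st$k600_md),
    stringsAsFactors = FALSE
  )
}

#' Mass-balance flux over a stream section
#'
#' Independent validation of k-based emissions over steep, rapidly degassing
#' sections: the upstream-downstream drop in dissolved concentration times
#' discharge gives the areal loss F = Q * 86.4 * (C_up - C_down) / A, where
#' 86.4 converts L s^-1 * uM to mmol d^-1.
#'
#' @param q Discharge (L s^-1).
#' @param c_up,c_down Dissolved concentrations up- and downstream (uM).
#' @param area_m2 Water surface area of the section (m^2).
#' @return Flux (mmol m^-2 d^-1).
#' @export
mass_balance_flux <- function(q, c_up, c_down, area_m2) {
  if (any(area_m2 <= 0)) stop("area must be positive", call. = FALSE)
  q * 86.4 * (c_up - c_down) / area_m2
}

#' Aggregate reach-day emissions to network summaries
#'
#' Sums reach-day mass emissions (ice-masked and missing days excluded, the
#' exclusion fraction reported) to annual totals per calendar year and to
#' mean annual totals, attaches the spatial-interpolation uncertainty bounds,
#' converts to CO2-equivalents, and tabulates the slope- and discharge-
#' category ratios. CH4 totals are reported in kg yr^-1 and CO2 totals in
#' Mg yr^-1, matching the conventional units for each gas.
#'
#' @param states Reach-day table with columns `reach_id`, `date`,
#'   `discharge_Ls`, `k600_md`, `flux_CH4`, `flux_CO2`, `mass_CH4_kg`,
#'   `mass_CO2_kg`, logical `excluded`.
#' @param reaches Reach table from [discretize()].
#' @param unc_ch4_pct,unc_co2_pct Uncertainty percentages from
#'   [uncertainty_pct()].
#' @param gwp Global warming potential for CH4 (default 28).
#' @return An `emission_summary` object (list with totals, bounds, mean
#'   areal fluxes, CO2-equivalents and category tables).
#' @export
aggregate_emissions <- function(states, reaches, unc_ch4_pct, unc_co2_pct,
                                gwp = 28) {
  ok <- !states$excluded & is.finite(states$mass_CH4_kg) &
    is.finite(states$mass_CO2_kg)
  excluded_fraction <- 1 - mean(ok)
  st <- states[ok, , drop = FALSE]
  yr <- format(as.Date(st$date), "%Y")
  years <- sort(unique(yr))
  tot_ch4 <- tapply(st$mass_CH4_kg, yr, sum)[years]
  tot_co2 <- tapply(st$mass_CO2_kg, yr, sum)[years] / 1000   # Mg
  annual <- data.frame(year = years,
                       ch4_kg = as.numeric(tot_ch4),
                       co2_mg = as.numeric(tot_co2))
  mean_ch4 <- mean(annual$ch4_kg)
  mean_co2 <- mean(annual$co2_mg)
  co2e <- co2_equivalents(mean_ch4, mean_co2, gwp)
  cum <- st[order(st$date), c("date", "mass_CH4_kg", "mass_CO2_kg")]
  daily <- do.call(rbind, lapply(split(cum, cum$date), function(d) {
    data.frame(date = d$date[1], ch4_kg = sum(d$mass_CH4_kg),
               co2_kg = sum(d$mass_CO2_kg))
  }))
  daily <- daily[order(daily$date), ]
  daily$cum_ch4_kg <- cumsum(daily$ch4_kg)
  daily$cum_co2_kg <- cumsum(daily$co2_kg)
  rownames(daily) <- NULL
  structure(list(
    annual = annual,
    mean_annual = list(
      ch4_kg = mean_ch4, co2_mg = mean_co2,
      ch4_bounds_kg = uncertainty_bounds(mean_ch4, unc_ch4_pct),
      co2_bounds_mg = uncertainty_bounds(mean_co2, unc_co2_pct)
    ),
    mean_flux = list(
      ch4_mmol_m2_d = mean(st$flux_CH4, na.rm = TRUE),
      co2_mmol_m2_d = mean(st$flux_CO2, na.rm = TRUE),
      ch4_bounds = uncertainty_bounds(mean(st$flux_CH4, na.rm = TRUE),
                                      unc_ch4_pct),
      co2_bounds = uncertainty_bounds(mean(st$flux_CO2, na.rm = TRUE),
                                      unc_co2_pct)
    ),
    co2_equivalents = co2e,
    uncertainty_pct = c(CH4 = unc_ch4_pct, CO2 = unc_co2_pct),
    gwp = gwp,
    excluded_fraction = excluded_fraction,
    n_reach_days = nrow(st),
    slope_table = category_ratios(states, reaches, "slope_category"),
    discharge_table = category_ratios(states, reaches, "discharge_bin"),
    daily = daily
  ), class = "emission_summary")
}

#' @export
print.emission_summary <- function(x, ...) {
  cat("<emission_summary>", x$n_reach_days, "reach-days (",
      round(100 * x$excluded_fraction, 1), "% excluded )\n")
  cat("Mean annual totals:\n")
  cat(sprintf("  CH4: %.1f kg yr^-1  (%.1f - %.1f)\n",
              x$mean_annual$ch4_kg, x$mean_annual$ch4_bounds_kg[["low"]],
              x$mean_annual$ch4_bounds_kg[["high"]]))
  cat(sprintf("  CO2: %.1f Mg yr^-1  (%.1f - %.1f)\n",
              x$mean_annual$co2_mg, x$mean_annual$co2_bounds_mg[["low"]],
              x$mean_annual$co2_bounds_mg[["high"]]))
  cat(sprintf("  CO2-eq: %.1f Mg yr^-1 (CH4 share %.1f %%, GWP %g)\n",
              x$co2_equivalents$total_mg_co2e_yr,
              x$co2_equivalents$ch4_share_pct, x$gwp))
  cat(sprintf("Mean areal flux: CH4 %.2f, CO2 %.0f mmol m^-2 d^-1\n",
              x$mean_flux$ch4_mmol_m2_d, x$mean_flux$co2_mmol_m2_d))
  cat("Slope-category ratios:\n")
  print(x$slope_table, row.names = FALSE, digits = 3)
  cat("Discharge-ratio categories:\n")
  print(x$discharge_table, row.names = FALSE, digits = 3)
  invisible(x)
}
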
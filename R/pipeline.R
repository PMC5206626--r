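# Configuration, CSV readers/writers and the end-to-end upscaling pipeline
# tying the modules into the published analysis sequence:
# discretise -> daily D = bA scaling -> velocity model -> k600 model with
# calibration and velocity cap -> concentration reconstruction -> per-reach
# daily fluxes -> network summaries.

#' Pipeline configuration
#'
#' All tunable constants of the upscaling in one place. Defaults are the
#' calibrated values shipped with the package: the velocity and k600
#' regression models of [velocity_model()] / [k600_model()], calibration
#' factor 0.89, velocity cap 0.7 m s^-1, reach elevation drop 0.5 m, sensor
#' despike threshold 20 %, GWP 28, slope floor 0.05 %, ice-run threshold 3
#' days, atmospheric mixing ratios 2.0 ppm CH4 / 405 ppm CO2. When
#' `refit_models` is TRUE (default) and an injection table is supplied, the
#' two regression models and the calibration factor are re-derived from the
#' injections instead of the defaults.
#'
#' @param ... Named overrides for any configuration field.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    velocity_model = velocity_model(),
    k600_model = k600_model(),
    calibration = 0.89,
    v_cap = 0.7,
    dz = 0.5,
    despike_threshold = 0.2,
    gwp = 28,
    slope_floor = 0.05,
    ice_min_run = 3,
    atm_ch4_ppm = 2.0,
    atm_co2_ppm = 405,
    bias_correct = TRUE,
    refit_models = TRUE
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    stop("unknown configuration field(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  cfg[names(dots)] <- dots
  structure(cfg, class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  cat("  calibration", x$calibration, "| v_cap", x$v_cap, "m/s | dz", x$dz,
      "m | slope floor", x$slope_floor, "% | GWP", x$gwp, "\n")
  cat("  atm CH4", x$atm_ch4_ppm, "ppm | atm CO2", x$atm_co2_ppm,
      "ppm | refit models:", x$refit_models, "\n")
  invisible(x)
}

.read_csv_checked <- function(path, required, date_cols = "date") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("file ", path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (dc in intersect(date_cols, names(df))) df[[dc]] <- as.Date(df[[dc]])
  df
}

#' Read and write the pipeline's CSV tables
#'
#' Plain UTF-8 CSV with a header row, ISO dates and decimal points. Each
#' reader validates the schema and names any missing columns. Schemas:
#' * profile: branch_id, distance_m, elevation_m, drainage_km2 (+ width_m)
#' * topology: branch_id, downstream_id (empty at the outlet)
#' * stations: station_id, date, q_Ls, drainage_km2
#' * air temperature: date, air_temp_C; water temperature: date,
#'   water_temp_C
#' * injections: reach_id, date, length_m, width_m, depth_m, slope_pct,
#'   travel_time_min, c_up, c_down, q_mean_Ls, q_diff_pct, water_temp_C
#' * surveys: gas, date, point_id, branch_id, distance_m, conc
#' * anchor points: anchor_id, branch_id, distance_m; anchor series: gas,
#'   date, anchor_id, conc
#'
#' @param path CSV file path.
#' @return A validated data frame.
#' @export
read_profile <- function(path) {
  .read_csv_checked(path, c("branch_id", "distance_m", "elevation_m",
                            "drainage_km2"), character(0))
}

#' @rdname read_profile
#' @export
read_topology <- function(path) {
  df <- .read_csv_checked(path, c("branch_id", "downstream_id"),
                          character(0))
  df$downstream_id[df$downstream_id == ""] <- NA
  df
}

#' @rdname read_profile
#' @export
read_stations <- function(path) {
  .read_csv_checked(path, c("station_id", "date", "q_Ls", "drainage_km2"))
}

#' @rdname read_profile
#' @export
read_air_temp <- function(path) {
  .read_csv_checked(path, c("date", "air_temp_C"))
}

#' @rdname read_profile
#' @export
read_water_temp <- function(path) {
  .read_csv_checked(path, c("date", "water_temp_C"))
}

#' @rdname read_profile
#' @export
read_injections <- function(path) {
  .read_csv_checked(path, c("reach_id", "length_m", "depth_m",
                            "travel_time_min", "c_up", "c_down",
                            "q_mean_Ls", "q_diff_pct", "water_temp_C"))
}

#' @rdname read_profile
#' @export
read_surveys <- function(path) {
  .read_csv_checked(path, c("gas", "date", "branch_id", "distance_m",
                            "conc"))
}

#' @rdname read_profile
#' @export
read_anchor_points <- function(path) {
  .read_csv_checked(path, c("anchor_id", "branch_id", "distance_m"),
                    character(0))
}

#' @rdname read_profile
#' @export
read_anchor_series <- function(path) {
  .read_csv_checked(path, c("gas", "date", "anchor_id", "conc"))
}

#' Write a synthetic catchment dataset as the pipeline's CSV files
#'
#' Writes profile.csv, topology.csv, stations.csv, air_temp.csv,
#' water_temp.csv, injections.csv, surveys.csv, anchor_points.csv and
#' anchors.csv into `dir` in exactly the dialects the readers consume.
#'
#' @param dataset Output of [gen_catchment_dataset()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of file paths written.
#' @export
write_catchment_dataset <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  w <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    p
  }
  inj <- dataset$injections
  inj$width_m <- dataset$reaches$width_m[match(inj$reach_id,
                                               dataset$reaches$reach_id)]
  paths <- c(
    w(dataset$network$profile, "profile.csv"),
    w(dataset$network$topology, "topology.csv"),
    w(dataset$discharge$stations, "stations.csv"),
    w(dataset$discharge$air_temp, "air_temp.csv"),
    w(dataset$discharge$water_temp, "water_temp.csv"),
    w(inj[, c("reach_id", "date", "length_m", "width_m", "depth_m",
              "slope_pct", "travel_time_min", "c_up", "c_down",
              "q_mean_Ls", "q_diff_pct", "water_temp_C")],
      "injections.csv"),
    w(dataset$conc$surveys, "surveys.csv"),
    w(dataset$conc$anchor_points, "anchor_points.csv"),
    w(dataset$conc$anchors, "anchors.csv")
  )
  invisible(paths)
}

#' Read a catchment dataset directory written by [write_catchment_dataset()]
#'
#' @param dir Directory containing the CSV files.
#' @return A list with elements `profile`, `topology`, `stations`,
#'   `air_temp`, `water_temp`, `injections`, `surveys`, `anchor_points`,
#'   `anchors`, suitable for [run_emission_pipeline()].
#' @export
read_catchment_dataset <- function(dir) {
  list(
    profile = read_profile(file.path(dir, "profile.csv")),
    topology = read_topology(file.path(dir, "topology.csv")),
    stations = read_stations(file.path(dir, "stations.csv")),
    air_temp = read_air_temp(file.path(dir, "air_temp.csv")),
    water_temp = read_water_temp(file.path(dir, "water_temp.csv")),
    injections = read_injections(file.path(dir, "injections.csv")),
    surveys = read_surveys(file.path(dir, "surveys.csv")),
    anchor_points = read_anchor_points(file.path(dir, "anchor_points.csv")),
    anchors = read_anchor_series(file.path(dir, "anchors.csv"))
  )
}

# per-reach k600 with the velocity cap: below the cap the calibrated model;
# above it the running maximum of below-cap values up to that date
.k600_with_cap <- function(velocity_ms, slope_pct, model, calibration,
                           bias_correct, v_cap, slope_floor) {
  base <- predict_k600(pmin(velocity_ms, v_cap), slope_pct, model,
                       calibration = calibration,
                       bias_correct = bias_correct, v_cap = v_cap,
                       slope_floor = slope_floor)
  below <- ifelse(velocity_ms <= v_cap, base, -Inf)
  run_max <- cummax(below)
  out <- ifelse(velocity_ms <= v_cap, base,
                ifelse(is.finite(run_max), run_max, base))
  out
}

#' Run the full stream-network emission upscaling
#'
#' Executes the published analysis sequence on a set of input tables (see
#' [read_catchment_dataset()] for the expected elements):
#' 1. discretise the longitudinal profile into reaches of `dz` elevation
#'    drop;
#' 2. fit the daily discharge - drainage-area scaling D = bA across the
#'    gauging stations and assign every reach a daily discharge;
#' 3. predict daily reach velocities (velocity model, smearing-corrected);
#' 4. predict daily reach k600 (k600 model, smearing-corrected, times the
#'    calibration factor), holding velocities at the calibrated cap and
#'    substituting the reach-specific below-cap maximum above it - if an
#'    injection table is supplied and `refit_models` is TRUE, both models
#'    and the calibration factor are first re-derived from the injections;
#' 5. reconstruct daily CH4 and CO2 concentrations per reach from the
#'    spatial surveys and anchor series;
#' 6. compute per-reach-day fluxes and mass emissions, excluding ice
#'    periods (air temperature below 0 degC for more than `ice_min_run`
#'    consecutive days);
#' 7. aggregate to annual totals, CO2-equivalents, uncertainty bounds and
#'    category ratio tables.
#'
#' @param inputs List of input tables: `profile`, `topology`, `stations`,
#'   `air_temp`, `water_temp`, `surveys`, `anchor_points`, `anchors` and
#'   optionally `injections`.
#' @param config A [pipeline_config()].
#' @return List with `reaches`, `scaling`, `models` (velocity model, k600
#'   model, calibration factor), `injection_results`, `ratios` and
#'   `uncertainty_pct` per gas, the reach-day `states` table, and the
#'   `summary` ([aggregate_emissions()] output).
#' @export
run_emission_pipeline <- function(inputs, config = pipeline_config()) {
  needed <- c("profile", "topology", "stations", "air_temp", "water_temp",
              "surveys", "anchor_points", "anchors")
  missing_in <- setdiff(needed, names(inputs))
  if (length(missing_in)) {
    stop("pipeline inputs are missing element(s): ",
         paste(missing_in, collapse = ", "), call. = FALSE)
  }

  reaches <- discretize(inputs$profile, config$dz)
  scaling <- fit_daily_scaling(inputs$stations)
  ice <- ice_mask(inputs$air_temp, config$ice_min_run)

  # models: refit from injections when available
  vmod <- config$velocity_model
  kmod <- config$k600_model
  calib <- config$calibration
  inj_res <- NULL
  if (!is.null(inputs$injections) && isTRUE(config$refit_models)) {
    inj_res <- injections_k600(inputs$injections)
    fit_dat <- data.frame(velocity_ms = inj_res$velocity_ms,
                          discharge_Ls = inj_res$q_mean_Ls,
                          slope_pct = inj_res$slope_pct,
                          k600_md = inj_res$k600_md)
    vmod <- fit_velocity_model(fit_dat, config$slope_floor)
    kmod <- fit_k600_model(fit_dat, config$slope_floor)
    modelled <- predict_k600(fit_dat$velocity_ms, fit_dat$slope_pct, kmod,
                             calibration = 1,
                             bias_correct = config$bias_correct,
                             v_cap = config$v_cap,
                             slope_floor = config$slope_floor)
    calib <- calibration_factor(fit_dat$k600_md, modelled)
  }

  dates <- scaling$date
  n_d <- length(dates)
  n_r <- nrow(reaches)
  states <- data.frame(
    reach_id = rep(reaches$reach_id, each = n_d),
    date = rep(dates, n_r),
    stringsAsFactors = FALSE
  )
  b <- scaling$b[match(states$date, scaling$date)]
  a <- reaches$drainage_km2[match(states$reach_id, reaches$reach_id)]
  s <- reaches$slope_pct[match(states$reach_id, reaches$reach_id)]
  states$discharge_Ls <- reach_discharge(a, b)
  states$velocity_ms <- predict_velocity(states$discharge_Ls, s, vmod,
                                         bias_correct = config$bias_correct,
                                         slope_floor = config$slope_floor)
  states$k600_md <- NA_real_
  for (r in reaches$reach_id) {
    i <- states$reach_id == r
    states$k600_md[i] <- .k600_with_cap(
      states$velocity_ms[i], s[i][1], kmod, calib, config$bias_correct,
      config$v_cap, config$slope_floor)
  }

  # concentration reconstruction per gas
  ratios <- list()
  unc <- c(CH4 = NA_real_, CO2 = NA_real_)
  conc_cols <- list()
  for (gas in c("CH4", "CO2")) {
    sv <- inputs$surveys[inputs$surveys$gas == gas, , drop = FALSE]
    an <- inputs$anchors[inputs$anchors$gas == gas, , drop = FALSE]
    if (!nrow(sv) || !nrow(an)) {
      stop("no survey or anchor data for ", gas, call. = FALSE)
    }
    interp <- do.call(rbind, lapply(split(sv, as.character(sv$date)),
      function(d) {
        out <- spatial_interpolate(d, reaches, inputs$topology)
        out$date <- d$date[1]
        out
      }))
    assignment <- assign_anchors(reaches, inputs$anchor_points,
                                 inputs$topology)
    rat <- relative_ratios(interp, an, assignment)
    ratios[[gas]] <- rat
    unc[[gas]] <- uncertainty_pct(rat$cv)
    rec <- temporal_reconstruct(an, rat, dates)
    key <- paste(rec$reach_id, rec$date)
    conc_cols[[gas]] <- rec$conc[match(paste(states$reach_id, states$date),
                                       key)]
  }
  states$conc_CH4 <- conc_cols$CH4
  states$conc_CO2 <- conc_cols$CO2

  states$water_temp_C <-
    inputs$water_temp$water_temp_C[match(states$date,
                                         inputs$water_temp$date)]
  states$excluded <- ice$excluded[match(states$date, ice$date)]

  area <- reaches$area_m2[match(states$reach_id, reaches$reach_id)]
  e_ch4 <- reach_day_emission(states$k600_md, states$water_temp_C,
                              states$conc_CH4, config$atm_ch4_ppm, "CH4",
                              area)
  e_co2 <- reach_day_emission(states$k600_md, states$water_temp_C,
                              states$conc_CO2, config$atm_co2_ppm, "CO2",
                              area)
  states$flux_CH4 <- e_ch4$flux_mmol_m2_d
  states$flux_CO2 <- e_co2$flux_mmol_m2_d
  states$mass_CH4_kg <- e_ch4$mass_kg_d
  states$mass_CO2_kg <- e_co2$mass_kg_d

  summary <- aggregate_emissions(states, reaches,
                                 unc_ch4_pct = unc[["CH4"]],
                                 unc_co2_pct = unc[["CO2"]],
                                 gwp = config$gwp)
  list(reaches = reaches, scaling = scaling,
       models = list(velocity = vmod, k600 = kmod, calibration = calib),
       injection_results = inj_res,
       ratios = ratios, uncertainty_pct = unc,
       states = states, summary = summary)
}
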
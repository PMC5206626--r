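# Stream-network model: elevation-based reach discretisation, daily
# drainage-area discharge scaling, and log-linear regression models
# predicting water velocity and k600 for every reach and day.

.slope_breaks <- c(0, 1, 2, 4, 6, Inf)
.slope_labels <- c("S1", "S2", "S3", "S4", "S5")

#' Slope category of a reach
#'
#' Channel slopes are grouped into the five categories used for hot-spot
#' summaries: S1 (0-1 %), S2 (1-2 %), S3 (2-4 %), S4 (4-6 %), S5 (>= 6 %,
#' observed up to ~21 % in steep cascade reaches). Intervals are half-open
#' and lower-inclusive, so a slope of exactly 1 % falls in S2.
#'
#' @param slope_pct Channel slope (%), >= 0.
#' @return Factor with levels S1-S5.
#' @export
slope_category <- function(slope_pct) {
  if (any(slope_pct < 0)) stop("slope must be non-negative", call. = FALSE)
  cut(slope_pct, breaks = .slope_breaks, labels = .slope_labels,
      right = FALSE, include.lowest = TRUE)
}

#' Discretise a longitudinal stream profile into reaches
#'
#' Splits each branch of the network into contiguous reaches that each span a
#' fixed elevation drop `dz` (default 0.5 m), so reaches are long where the
#' channel is flat and short where it is steep. The final partial reach (and
#' any branch whose total drop is below `dz`) is kept. Local elevation rises
#' - DEM noise in an extracted profile - are flattened to zero drop with a
#' warning before segmentation. Reach slope is 100 * actual drop / length;
#' width is interpolated from the profile at the reach midpoint, surface area
#' is length x width, and drainage area is taken at the downstream end.
#'
#' @param profile Data frame with columns `branch_id`, `distance_m` (along
#'   the branch, increasing downstream), `elevation_m`, `drainage_km2` and
#'   optionally `width_m`.
#' @param dz Elevation drop per reach (m), default 0.5.
#' @return Data frame of reaches: `reach_id`, `branch_id`, `start_m`,
#'   `end_m`, `midpoint_m`, `length_m`, `drop_m`, `slope_pct`,
#'   `slope_category`, `width_m`, `area_m2`, `drainage_km2`.
#' @export
discretize <- function(profile, dz = 0.5) {
  required <- c("branch_id", "distance_m", "elevation_m", "drainage_km2")
  missing_cols <- setdiff(required, names(profile))
  if (length(missing_cols)) {
    stop("profile is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (dz <= 0) stop("dz must be positive", call. = FALSE)
  has_width <- "width_m" %in% names(profile)
  out <- list()
  flattened <- 0L
  for (b in unique(profile$branch_id)) {
    pp <- profile[profile$branch_id == b, , drop = FALSE]
    pp <- pp[order(pp$distance_m), , drop = FALSE]
    if (nrow(pp) < 2) {
      stop("branch ", b, " has fewer than 2 profile points", call. = FALSE)
    }
    el <- cummin(pp$elevation_m)
    flattened <- flattened + sum(el < pp$elevation_m)
    drop_cum <- el[1] - el               # non-decreasing cumulative drop
    total_drop <- drop_cum[length(drop_cum)]
    total_len <- pp$distance_m[nrow(pp)] - pp$distance_m[1]
    if (total_len <= 0) stop("branch ", b, " has zero length", call. = FALSE)

    n_full <- floor(total_drop / dz + 1e-9)
    cuts <- seq_len(n_full) * dz
    cuts <- cuts[cuts < total_drop - 1e-9]
    if (length(cuts)) {
      # invert the (non-decreasing) cumulative-drop curve; on flat stretches
      # the boundary is placed at the first point reaching the target drop
      cut_d <- stats::approx(drop_cum, pp$distance_m, xout = cuts,
                             ties = min)$y
    } else {
      cut_d <- numeric(0)
    }
    bounds <- c(pp$distance_m[1], cut_d, pp$distance_m[nrow(pp)])
    bounds <- bounds[!duplicated(round(bounds, 9))]
    drop_at <- stats::approx(pp$distance_m, drop_cum, xout = bounds,
                             ties = "ordered")$y
    n_r <- length(bounds) - 1
    len <- diff(bounds)
    drp <- diff(drop_at)
    keep <- len > 1e-9
    len <- len[keep]; drp <- drp[keep]
    start <- bounds[-length(bounds)][keep]
    end <- (bounds[-1])[keep]
    mid <- (start + end) / 2
    slope <- 100 * drp / len
    width <- if (has_width) {
      stats::approx(pp$distance_m, pp$width_m, xout = mid, rule = 2,
                    ties = "ordered")$y
    } else NA_real_
    drainage <- stats::approx(pp$distance_m, pp$drainage_km2, xout = end,
                              rule = 2, ties = "ordered")$y
    out[[length(out) + 1]] <- data.frame(
      reach_id = sprintf("%s_r%02d", b, seq_along(len)),
      branch_id = b,
      start_m = start, end_m = end, midpoint_m = mid,
      length_m = len, drop_m = drp, slope_pct = slope,
      slope_category = slope_category(slope),
      width_m = width,
      area_m2 = len * width,
      drainage_km2 = drainage,
      stringsAsFactors = FALSE
    )
  }
  if (flattened > 0) {
    warning(flattened, " locally rising profile point(s) flattened to zero",
            " drop before discretisation", call. = FALSE)
  }
  do.call(rbind, out)
}

#' Fit the daily discharge - drainage-area scaling D = bA
#'
#' For each day, fits the proportionality D = b * A through the origin across
#' the gauging stations by least squares (b = sum(A*D)/sum(A^2)), with the
#' through-origin R^2 = 1 - SS_res/sum(D^2). Days with fewer than two
#' stations with distinct drainage areas raise an error.
#'
#' @param stations Data frame with columns `station_id`, `date`, `q_Ls`,
#'   `drainage_km2`.
#' @return Data frame with one row per day: `date`, `b` (L s^-1 km^-2),
#'   `r2`, `n_stations`.
#' @export
fit_daily_scaling <- function(stations) {
  required <- c("station_id", "date", "q_Ls", "drainage_km2")
  missing_cols <- setdiff(required, names(stations))
  if (length(missing_cols)) {
    stop("station table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  res <- lapply(split(stations, stations$date), function(d) {
    a <- d$drainage_km2; q <- d$q_Ls
    if (length(unique(a)) < 2) {
      stop("need >= 2 stations with distinct drainage areas on ",
           d$date[1], call. = FALSE)
    }
    b <- sum(a * q) / sum(a^2)
    r2 <- 1 - sum((q - b * a)^2) / sum(q^2)
    data.frame(date = d$date[1], b = b, r2 = r2, n_stations = nrow(d))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out[order(out$date), , drop = FALSE]
}

#' Daily discharge of a reach from the drainage-area scaling
#'
#' D = b * A with the reach's upstream drainage area; linear in A by
#' construction.
#'
#' @param drainage_km2 Upstream drainage area (km^2).
#' @param b Daily scaling constant (L s^-1 km^-2).
#' @return Discharge (L s^-1).
#' @export
reach_discharge <- function(drainage_km2, b) {
  drainage_km2 * b
}

#' Smearing (Newman) back-transform factor
#'
#' Retransformation of predictions from a log10-scale regression to original
#' units is biased low; under normal residuals the unbiased back-transform
#' multiplies 10^yhat by exp(MSE * ln(10)^2 / 2), where MSE is the residual
#' mean square on the log10 scale. Zero MSE gives a factor of exactly 1.
#'
#' @param mse Residual mean square of the log10-scale regression.
#' @return Multiplicative correction factor (>= 1).
#' @export
newman_factor <- function(mse) {
  if (any(mse < 0)) stop("MSE must be non-negative", call. = FALSE)
  exp(mse * log(10)^2 / 2)
}

.new_regression_model <- function(coefficients, mse, adj_r2, n, response,
                                  terms, se = NULL) {
  structure(list(coefficients = coefficients, se = se, mse = mse,
                 adj_r2 = adj_r2, n = n, response = response, terms = terms),
            class = "regression_model")
}

#' @export
print.regression_model <- function(x, ...) {
  cat("<regression_model>", x$response, "~",
      paste(x$terms, collapse = " + "), "\n")
  print(round(x$coefficients, 4))
  cat("  n =", x$n, " adj R2 =", round(x$adj_r2, 3),
      " MSE(log10) =", signif(x$mse, 3), "\n")
  invisible(x)
}

#' Default velocity and k600 regression models
#'
#' The calibrated models shipped as defaults, fitted to the tracer-injection
#' campaigns in the hemiboreal catchment the package was developed for:
#'
#' * Model 1: log10 V = -1.323 + 0.466 log10 D + 0.056 log10 S
#'   (n = 21, adj R2 = 0.91, MSE = 0.006)
#' * Model 2: log10 k600 = 0.319 + 2.110 V + 1.026 log10 S
#'   (n = 53, adj R2 = 0.92, MSE = 0.050)
#'
#' with V in m s^-1, D in L s^-1, S in % and k600 in m d^-1. Use
#' [fit_velocity_model()] / [fit_k600_model()] to refit to local data.
#'
#' @param coefficients Named numeric vector of model coefficients.
#' @param mse Residual mean square on the log10 scale.
#' @param adj_r2 Adjusted R^2.
#' @param n Number of observations behind the fit.
#' @return A `regression_model` object.
#' @export
velocity_model <- function(coefficients = c(intercept = -1.323,
                                            log10_discharge = 0.466,
                                            log10_slope = 0.056),
                           mse = 0.006, adj_r2 = 0.91, n = 21) {
  .new_regression_model(coefficients, mse, adj_r2, n, "log10_velocity",
                        c("log10_discharge", "log10_slope"))
}

#' @rdname velocity_model
#' @export
k600_model <- function(coefficients = c(intercept = 0.319,
                                        velocity = 2.110,
                                        log10_slope = 1.026),
                       mse = 0.050, adj_r2 = 0.92, n = 53) {
  .new_regression_model(coefficients, mse, adj_r2, n, "log10_k600",
                        c("velocity", "log10_slope"))
}

.floor_slope <- function(slope_pct, slope_floor) {
  if (any(slope_pct < 0)) stop("slope must be non-negative", call. = FALSE)
  pmax(slope_pct, slope_floor)
}

#' Predict water velocity from discharge and slope
#'
#' Evaluates the log10-linear velocity model and back-transforms to m s^-1,
#' optionally applying the smearing correction derived from the model's MSE
#' (see [newman_factor()]). Slopes below `slope_floor` (default 0.05 %) are
#' floored before taking log10, since the flattest category starts at 0 %.
#'
#' @param discharge_Ls Discharge (L s^-1), > 0.
#' @param slope_pct Channel slope (%), >= 0 (floored).
#' @param model A velocity `regression_model`, default [velocity_model()].
#' @param bias_correct Apply the smearing back-transform correction
#'   (default TRUE).
#' @param slope_floor Minimum slope (%) used in log10 terms.
#' @return Velocity (m s^-1), vectorised.
#' @export
predict_velocity <- function(discharge_Ls, slope_pct,
                             model = velocity_model(),
                             bias_correct = TRUE, slope_floor = 0.05) {
  if (any(discharge_Ls <= 0)) {
    stop("discharge must be positive", call. = FALSE)
  }
  s <- .floor_slope(slope_pct, slope_floor)
  co <- model$coefficients
  log10v <- co[["intercept"]] + co[["log10_discharge"]] * log10(discharge_Ls) +
    co[["log10_slope"]] * log10(s)
  v <- 10^log10v
  if (bias_correct) v <- v * newman_factor(model$mse)
  v
}

#' Predict k600 from velocity and slope
#'
#' Evaluates the log10-linear k600 model, back-transforms (optionally with
#' the smearing correction), and multiplies by the measured-vs-modelled
#' calibration factor (default 0.89, derived with [calibration_factor()]).
#' The model is only applied within the velocity range it was calibrated for:
#' for velocities above `v_cap` (default 0.7 m s^-1) the reach-specific
#' maximum k600 previously modelled below the cap (`reach_max`) is returned
#' instead of an extrapolation; if no such maximum is available the model is
#' evaluated at the cap with a warning.
#'
#' @param velocity_ms Water velocity (m s^-1), >= 0.
#' @param slope_pct Channel slope (%), >= 0 (floored as in
#'   [predict_velocity()]).
#' @param model A k600 `regression_model`, default [k600_model()].
#' @param calibration Multiplicative calibration factor (default 0.89).
#' @param bias_correct Apply the smearing correction (default TRUE).
#' @param v_cap Velocity cap (m s^-1) of the calibrated range.
#' @param reach_max Reach-specific maximum below-cap k600 (m d^-1), recycled;
#'   used for observations with velocity above the cap.
#' @param slope_floor Minimum slope (%) used in log10 terms.
#' @return k600 (m d^-1), vectorised.
#' @export
predict_k600 <- function(velocity_ms, slope_pct, model = k600_model(),
                         calibration = 0.89, bias_correct = TRUE,
                         v_cap = 0.7, reach_max = NULL, slope_floor = 0.05) {
  if (any(velocity_ms < 0)) stop("velocity must be >= 0", call. = FALSE)
  s <- .floor_slope(slope_pct, slope_floor)
  v_eval <- pmin(velocity_ms, v_cap)
  co <- model$coefficients
  log10k <- co[["intercept"]] + co[["velocity"]] * v_eval +
    co[["log10_slope"]] * log10(s)
  k <- 10^log10k
  if (bias_correct) k <- k * newman_factor(model$mse)
  k <- calibration * k
  over <- velocity_ms > v_cap
  if (any(over)) {
    if (is.null(reach_max)) {
      warning(sum(over), " velocity value(s) above the ", v_cap,
              " m s^-1 cap with no reach maximum available;",
              " using the model evaluated at the cap", call. = FALSE)
    } else {
      rm_ <- rep_len(reach_max, length(k))
      use <- over & is.finite(rm_)
      k[use] <- rm_[use]
      if (any(over & !is.finite(rm_))) {
        warning(sum(over & !is.finite(rm_)),
                " above-cap velocity value(s) without a finite reach",
                " maximum; using the model evaluated at the cap",
                call. = FALSE)
      }
    }
  }
  k
}

.fit_log10_model <- function(data, formula, response, terms, slope_floor) {
  fit <- stats::lm(formula, data = data)
  if (any(is.na(stats::coef(fit)))) {
    stop("regression design is rank deficient", call. = FALSE)
  }
  sm <- summary(fit)
  co <- stats::coef(fit)
  names(co) <- c("intercept", terms)
  se <- sm$coefficients[, "Std. Error"]
  names(se) <- names(co)
  .new_regression_model(co, sm$sigma^2, sm$adj.r.squared, nrow(data),
                        response, terms, se = se)
}

.check_fit_data <- function(data, cols) {
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols)) {
    stop("model data is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(data) < 10) {
    stop("need >= 10 observations to fit", call. = FALSE)
  }
  if (length(unique(slope_category(data$slope_pct))) < 2) {
    stop("observations must span more than one slope category", call. = FALSE)
  }
}

#' Fit the velocity and k600 regression models
#'
#' Ordinary least squares on the transformed scales used throughout:
#' `fit_velocity_model()` regresses log10 velocity on log10 discharge and
#' log10 slope; `fit_k600_model()` regresses log10 k600 on (untransformed)
#' velocity and log10 slope. Requires at least 10 observations spanning more
#' than one slope category. Returns a `regression_model` carrying the
#' coefficients, the residual mean square on the log10 scale (which drives
#' the smearing correction), the adjusted R^2 and n.
#'
#' @param data Data frame with columns `velocity_ms`, `slope_pct` and, for
#'   the velocity model, `discharge_Ls`, or, for the k600 model, `k600_md`.
#'   Rows with non-finite response values (e.g. flagged negative-rate
#'   injections) are dropped.
#' @param slope_floor Minimum slope (%) used in log10 terms.
#' @return A `regression_model`.
#' @export
fit_velocity_model <- function(data, slope_floor = 0.05) {
  .check_fit_data(data, c("velocity_ms", "discharge_Ls", "slope_pct"))
  data <- data[is.finite(data$velocity_ms) & data$velocity_ms > 0, ,
               drop = FALSE]
  data$.ls <- log10(.floor_slope(data$slope_pct, slope_floor))
  .fit_log10_model(data,
                   log10(velocity_ms) ~ log10(discharge_Ls) + .ls,
                   "log10_velocity", c("log10_discharge", "log10_slope"),
                   slope_floor)
}

#' @rdname fit_velocity_model
#' @export
fit_k600_model <- function(data, slope_floor = 0.05) {
  .check_fit_data(data, c("k600_md", "velocity_ms", "slope_pct"))
  data <- data[is.finite(data$k600_md) & data$k600_md > 0, , drop = FALSE]
  data$.ls <- log10(.floor_slope(data$slope_pct, slope_floor))
  .fit_log10_model(data,
                   log10(k600_md) ~ velocity_ms + .ls,
                   "log10_k600", c("velocity", "log10_slope"),
                   slope_floor)
}

#' Measured-vs-modelled calibration factor
#'
#' Slope of the least-squares regression of measured on modelled values,
#' through the origin by default (a pure rescaling,
#' sum(xy)/sum(x^2) with x = modelled); set `intercept = TRUE` for the
#' ordinary regression slope. Applied multiplicatively to model predictions
#' to remove over- or under-estimation in the high range.
#'
#' @param measured,modelled Paired observations.
#' @param intercept Fit with an intercept (default FALSE).
#' @return The calibration slope.
#' @export
calibration_factor <- function(measured, modelled, intercept = FALSE) {
  ok <- is.finite(measured) & is.finite(modelled)
  measured <- measured[ok]; modelled <- modelled[ok]
  if (!length(measured)) stop("no finite pairs", call. = FALSE)
  if (intercept) {
    unname(stats::coef(stats::lm(measured ~ modelled))[2])
  } else {
    sum(measured * modelled) / sum(modelled^2)
  }
}

#' Ice-period exclusion mask
#'
#' Streams are treated as ice-covered (and excluded from flux integration)
#' on every day inside a run of more than `min_run` consecutive days with
#' mean air temperature below 0 degC.
#'
#' @param air_temp Data frame with columns `date` and `air_temp_C`, one row
#'   per day, sorted or not.
#' @param min_run Minimum run length (days) that triggers exclusion; runs of
#'   strictly more than this many sub-zero days are excluded. Default 3.
#' @return The input data frame (sorted by date) with a logical `excluded`
#'   column appended.
#' @export
ice_mask <- function(air_temp, min_run = 3) {
  required <- c("date", "air_temp_C")
  missing_cols <- setdiff(required, names(air_temp))
  if (length(missing_cols)) {
    stop("air temperature table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  air_temp <- air_temp[order(air_temp$date), , drop = FALSE]
  sub_zero <- air_temp$air_temp_C < 0
  r <- rle(sub_zero)
  excluded <- rep(r$values & r$lengths > min_run, r$lengths)
  air_temp$excluded <- excluded
  rownames(air_temp) <- NULL
  air_temp
}
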
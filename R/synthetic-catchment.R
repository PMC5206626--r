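# Synthetic catchment generator: branched stream networks, daily discharge,
# spatially structured supersaturated gas concentration fields and tracer
# injections with known ground truth, so every pipeline stage can be tested
# end-to-end without field data.
#
# The generated world mirrors the study design the package implements: a
# ~6.4 km hemiboreal network dominated by near-flat ditches (target ~90 % of
# stream area below 1 % slope) with short steep cascade sections (up to
# ~21 %), discharge proportional to drainage area with storm events, a
# separable concentration field (static spatial pattern x anchor time
# series; CH4 far more spatially variable than CO2), and whole-stream
# propane injections simulated from the groundwater-dilution physics.

#' Catchment scenario
#'
#' Parameter bundle describing a synthetic catchment. Defaults describe the
#' reference world: five branches totalling 6.4 km with areal slope-category
#' shares (90.5, 5.2, 2.6, 0.7, 0.9) %, two years of daily discharge scaled
#' to drainage area (base runoff 8 L s^-1 km^-2 plus storm events), four
#' gauging stations, 20 concentration survey points with 5 CH4 and 7 CO2
#' survey dates, 4 anchor stations (biweekly CH4, daily CO2), log10 noise
#' SDs sqrt(0.006) for velocity and sqrt(0.050) for k600 (the residual
#' scales of the shipped regression models), 5 % station discharge noise and
#' lognormal (sdlog 0.1) concentration observation noise.
#'
#' @param seed Integer seed governing all randomness.
#' @param noiseless If TRUE, all observation noise (station discharge,
#'   velocity, k600, concentration) is zeroed, so the pipeline should
#'   reproduce the generator truth exactly; the structural randomness
#'   (network shape, storm timing, spatial pattern) remains.
#' @param ... Named overrides for any scenario field.
#' @return An object of class `catchment_scenario`.
#' @export
catchment_scenario <- function(seed = 1L, noiseless = FALSE, ...) {
  sc <- list(
    seed = as.integer(seed),
    start_date = as.Date("2013-01-01"),
    n_years = 2,
    # network
    branch_lengths = c(H1 = 1200, H2 = 900, M1 = 1600, H3 = 1100, M2 = 1600),
    downstream = c(H1 = "M1", H2 = "M1", M1 = "M2", H3 = "M2", M2 = NA),
    slope_shares = c(S1 = 0.905, S2 = 0.052, S3 = 0.026, S4 = 0.007,
                     S5 = 0.009),
    slope_ranges = list(S1 = c(0.1, 0.9), S2 = c(1.05, 1.95),
                        S3 = c(2.1, 3.9), S4 = c(4.1, 5.9),
                        S5 = c(6.5, 21)),
    flat_piece_m = c(80, 250), steep_piece_m = c(8, 30),
    point_spacing_m = 20,
    outlet_elevation_m = 51,
    drainage_head = c(H1 = 0.05, H2 = 0.04, M1 = 1.4, H3 = 0.05, M2 = 3.1),
    drainage_end = c(H1 = 0.8, H2 = 0.6, M1 = 2.2, H3 = 0.9, M2 = 7.0),
    width_coef = 0.8, width_exp = 0.4,
    depth_coef = 0.18, depth_exp = 0.25,
    station_branches = c(G1 = "H1", G2 = "M1", G3 = "H3", G4 = "M2"),
    # discharge
    b0 = 8, b_seasonal_amp = 0.5, b_ar_phi = 0.8, b_ar_sd = 0.15,
    storms_per_year = 12, storm_mult = c(3, 10), storm_decay_d = 1.5,
    q_noise_sdlog = 0.05,
    # temperature
    air_mean = 7, air_amp = 10, air_noise_sd = 2,
    water_mean = 7, water_amp = 7, water_noise_sd = 0.5, water_min = 0.2,
    # hydraulics truth
    velocity_model = velocity_model(),
    k600_model = k600_model(),
    v_cap = 0.7, slope_floor = 0.05,
    velocity_log10_sd = sqrt(0.006), k600_log10_sd = sqrt(0.050),
    # concentrations
    n_survey_points = 20, n_anchors = 4,
    anchor_branches = c("H1", "M1", "H3", "M2"),
    n_ch4_surveys = 5, n_co2_surveys = 7,
    ch4_level_um = 1.5, co2_level_um = 150,
    ch4_spatial_sdlog = 1.0, co2_spatial_sdlog = 0.3,
    ch4_anchor_ar = c(phi = 0.7, sd = 0.35),
    co2_anchor_ar = c(phi = 0.9, sd = 0.05),
    ch4_cadence_d = 14,
    conc_noise_sdlog = 0.1,
    # injections
    n_injection_runs = 53, injection_c_up = 100,
    gw_fraction_range = c(0.0006, 0.005),
    # atmosphere / reporting
    atm_ch4_ppm = 2.0, atm_co2_ppm = 405, gwp = 28,
    ice_min_run = 3, dz = 0.5
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(sc))
  if (length(unknown)) {
    stop("unknown scenario field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  sc[names(dots)] <- dots
  if (noiseless) {
    sc$q_noise_sdlog <- 0
    sc$velocity_log10_sd <- 0
    sc$k600_log10_sd <- 0
    sc$conc_noise_sdlog <- 0
  }
  structure(sc, class = "catchment_scenario")
}

#' @export
print.catchment_scenario <- function(x, ...) {
  cat("<catchment_scenario> seed", x$seed, "-", x$n_years, "years,",
      length(x$branch_lengths), "branches,",
      sum(x$branch_lengths), "m of channel\n")
  cat("  noise: q", x$q_noise_sdlog, "| v(log10)",
      signif(x$velocity_log10_sd, 3), "| k600(log10)",
      signif(x$k600_log10_sd, 3), "| conc", x$conc_noise_sdlog, "\n")
  invisible(x)
}

.scenario_dates <- function(sc) {
  seq(sc$start_date, by = "day", length.out = round(sc$n_years * 365))
}

.ar1 <- function(n, phi, sd) {
  x <- numeric(n)
  x[1] <- stats::rnorm(1, 0, sd / sqrt(1 - phi^2))
  for (i in seq_len(n)[-1]) x[i] <- phi * x[i - 1] + stats::rnorm(1, 0, sd)
  x
}

#' Generate a synthetic stream network
#'
#' Builds the branched longitudinal profile: each branch is partitioned into
#' slope segments whose per-category length budgets equal the scenario's
#' areal slope-share targets (so the generated shares match by
#' construction), segment order is shuffled, and profile points are placed
#' every ~`point_spacing_m`. Elevations descend monotonically; drainage area
#' grows linearly along each branch and sums at confluences; width follows
#' the power law `width_coef * A^width_exp`.
#'
#' @param sc A [catchment_scenario()].
#' @return List with `profile` (branch_id, distance_m, elevation_m,
#'   drainage_km2, width_m), `topology` (branch_id, downstream_id) and
#'   `stations` (station_id, branch_id, distance_m, drainage_km2).
#' @export
gen_network <- function(sc) {
  set.seed(sc$seed + 1L)
  cats <- names(sc$slope_shares)
  branch_ids <- names(sc$branch_lengths)
  profiles <- list()
  branch_drop <- stats::setNames(numeric(length(branch_ids)), branch_ids)

  segments_for <- function(len_total) {
    segs <- list()
    for (cat in cats) {
      budget <- sc$slope_shares[[cat]] * len_total
      rng <- if (cat == "S1") sc$flat_piece_m else sc$steep_piece_m
      while (budget > 1e-6) {
        piece <- min(budget, stats::runif(1, rng[1], rng[2]))
        if (budget - piece < 2) piece <- budget
        segs[[length(segs) + 1]] <- data.frame(
          cat = cat, len = piece,
          slope = stats::runif(1, sc$slope_ranges[[cat]][1],
                               sc$slope_ranges[[cat]][2]))
        budget <- budget - piece
      }
    }
    segs <- do.call(rbind, segs)
    segs[sample.int(nrow(segs)), , drop = FALSE]
  }

  for (b in branch_ids) {
    len_b <- sc$branch_lengths[[b]]
    segs <- segments_for(len_b)
    # profile points: segment boundaries plus ~point_spacing subdivisions
    dist <- 0; elev_drop <- 0
    xs <- 0; drops <- 0
    for (i in seq_len(nrow(segs))) {
      n_sub <- max(1, ceiling(segs$len[i] / sc$point_spacing_m))
      step <- segs$len[i] / n_sub
      for (j in seq_len(n_sub)) {
        dist <- dist + step
        elev_drop <- elev_drop + step * segs$slope[i] / 100
        xs <- c(xs, dist)
        drops <- c(drops, elev_drop)
      }
    }
    branch_drop[b] <- drops[length(drops)]
    a_head <- sc$drainage_head[[b]]; a_end <- sc$drainage_end[[b]]
    a <- a_head + (a_end - a_head) * xs / max(xs)
    profiles[[b]] <- data.frame(
      branch_id = b, distance_m = xs, drop_m = drops,
      drainage_km2 = a, width_m = sc$width_coef * a^sc$width_exp,
      stringsAsFactors = FALSE)
  }

  # absolute elevations: every tributary ends at the head of its downstream
  # branch, so head elevations accumulate upstream from the outlet
  head_elev <- stats::setNames(numeric(length(branch_ids)), branch_ids)
  remaining <- branch_ids
  while (length(remaining)) {
    for (b in remaining) {
      dn <- sc$downstream[[b]]
      if (is.na(dn)) {
        head_elev[b] <- sc$outlet_elevation_m + branch_drop[b]
        remaining <- setdiff(remaining, b)
      } else if (!(dn %in% remaining)) {
        head_elev[b] <- head_elev[dn] + branch_drop[b]
        remaining <- setdiff(remaining, b)
      }
    }
  }
  profile <- do.call(rbind, lapply(branch_ids, function(b) {
    p <- profiles[[b]]
    p$elevation_m <- head_elev[b] - p$drop_m
    p[, c("branch_id", "distance_m", "elevation_m", "drainage_km2",
          "width_m")]
  }))
  rownames(profile) <- NULL
  topology <- data.frame(branch_id = branch_ids,
                         downstream_id = unname(sc$downstream[branch_ids]),
                         stringsAsFactors = FALSE)
  stations <- data.frame(
    station_id = names(sc$station_branches),
    branch_id = unname(sc$station_branches),
    distance_m = unname(sc$branch_lengths[sc$station_branches]),
    drainage_km2 = unname(sc$drainage_end[sc$station_branches]),
    stringsAsFactors = FALSE)
  list(profile = profile, topology = topology, stations = stations)
}

#' Generate daily discharge, air and water temperature
#'
#' The true daily runoff coefficient b(t) (L s^-1 km^-2) combines a seasonal
#' cycle, lognormal AR(1) persistence and storm events with exponentially
#' decaying multipliers, so that days with discharge more than four times
#' the mean occur. Station discharges are D = b * A times multiplicative
#' lognormal noise. Air temperature has a seasonal cycle crossing 0 degC in
#' winter (driving the ice mask); water temperature is a damped seasonal
#' cycle floored just above zero.
#'
#' @param sc A [catchment_scenario()].
#' @param network Output of [gen_network()].
#' @return List with `daily` (date, b_true), `stations` (station_id, date,
#'   q_Ls, drainage_km2), `air_temp` (date, air_temp_C), `water_temp`
#'   (date, water_temp_C).
#' @export
gen_discharge <- function(sc, network) {
  set.seed(sc$seed + 2L)
  dates <- .scenario_dates(sc)
  n <- length(dates)
  doy <- as.integer(format(dates, "%j"))
  season <- 1 + sc$b_seasonal_amp * sin(2 * pi * (doy + 280) / 365)
  z <- .ar1(n, sc$b_ar_phi, sc$b_ar_sd)
  storm <- numeric(n)
  n_ev <- stats::rpois(1, sc$storms_per_year * sc$n_years)
  ev_days <- sample.int(n, n_ev)
  ev_mult <- stats::runif(n_ev, sc$storm_mult[1], sc$storm_mult[2])
  for (e in seq_len(n_ev)) {
    idx <- ev_days[e]:min(n, ev_days[e] + 6)
    storm[idx] <- storm[idx] +
      ev_mult[e] * exp(-(idx - ev_days[e]) / sc$storm_decay_d)
  }
  b_true <- sc$b0 * season * exp(z) * (1 + storm)

  air <- sc$air_mean + sc$air_amp * sin(2 * pi * (doy - 105) / 365) +
    stats::rnorm(n, 0, sc$air_noise_sd)
  water <- pmax(sc$water_min,
                sc$water_mean + sc$water_amp *
                  sin(2 * pi * (doy - 120) / 365) +
                  stats::rnorm(n, 0, sc$water_noise_sd))

  st <- network$stations
  stations <- do.call(rbind, lapply(seq_len(nrow(st)), function(i) {
    data.frame(station_id = st$station_id[i], date = dates,
               q_Ls = b_true * st$drainage_km2[i] *
                 exp(stats::rnorm(n, 0, sc$q_noise_sdlog)),
               drainage_km2 = st$drainage_km2[i],
               stringsAsFactors = FALSE)
  }))
  list(daily = data.frame(date = dates, b_true = b_true),
       stations = stations,
       air_temp = data.frame(date = dates, air_temp_C = air),
       water_temp = data.frame(date = dates, water_temp_C = water))
}

# model-surface evaluation without back-transform corrections (the raw
# regression equations define the generator's truth)
.eval_velocity <- function(sc, d, s) {
  co <- sc$velocity_model$coefficients
  10^(co[["intercept"]] + co[["log10_discharge"]] * log10(d) +
        co[["log10_slope"]] * log10(pmax(s, sc$slope_floor)))
}
.eval_k600 <- function(sc, v, s) {
  co <- sc$k600_model$coefficients
  10^(co[["intercept"]] + co[["velocity"]] * v +
        co[["log10_slope"]] * log10(pmax(s, sc$slope_floor)))
}

#' Generate the true reach-day hydraulics
#'
#' For every reach and day: discharge D = b_true * A, velocity from the
#' scenario's velocity model surface with lognormal (log10 SD
#' `velocity_log10_sd`) scatter, and k600 from the k600 model surface with
#' its own scatter. Above the velocity cap the reach-specific maximum
#' below-cap k600 seen so far is used (the same rule the upscaling applies),
#' implemented here as an explicit day-by-day loop that doubles as a
#' brute-force oracle for the pipeline's vectorised version.
#'
#' @param sc A [catchment_scenario()].
#' @param reaches Reach table from [discretize()].
#' @param daily `daily` element of [gen_discharge()].
#' @return Data frame `reach_id`, `date`, `discharge_Ls`, `velocity_ms`,
#'   `k600_md`.
#' @export
gen_hydraulics <- function(sc, reaches, daily) {
  set.seed(sc$seed + 3L)
  n_d <- nrow(daily)
  out <- vector("list", nrow(reaches))
  for (i in seq_len(nrow(reaches))) {
    d <- daily$b_true * reaches$drainage_km2[i]
    v <- .eval_velocity(sc, d, reaches$slope_pct[i]) *
      10^stats::rnorm(n_d, 0, sc$velocity_log10_sd)
    eps_k <- stats::rnorm(n_d, 0, sc$k600_log10_sd)
    k <- numeric(n_d)
    mx <- -Inf
    for (j in seq_len(n_d)) {
      if (v[j] <= sc$v_cap) {
        k[j] <- .eval_k600(sc, v[j], reaches$slope_pct[i]) * 10^eps_k[j]
        mx <- max(mx, k[j])
      } else {
        k[j] <- if (is.finite(mx)) mx else
          .eval_k600(sc, sc$v_cap, reaches$slope_pct[i]) * 10^eps_k[j]
      }
    }
    out[[i]] <- data.frame(reach_id = reaches$reach_id[i], date = daily$date,
                           discharge_Ls = d, velocity_ms = v, k600_md = k,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# independent spatial interpolation used to define the generator's true
# per-reach pattern (and serving as the brute-force oracle for
# spatial_interpolate): per-branch linear interpolation over node values,
# drainage-weighted mixing at confluences, constant beyond terminal nodes
.truth_spatial <- function(nodes, reaches, topology) {
  meta <- .branch_meta(reaches)
  ord <- .topo_order(topology)
  end_val <- stats::setNames(rep(NA_real_, nrow(meta)), meta$branch_id)
  vals <- stats::setNames(rep(NA_real_, nrow(reaches)), reaches$reach_id)
  for (b in ord) {
    len_b <- meta$length_m[meta$branch_id == b]
    nb <- nodes[nodes$branch_id == b, , drop = FALSE]
    xs <- nb$distance_m; vs <- nb$value
    ups <- topology$branch_id[!is.na(topology$downstream_id) &
                                topology$downstream_id == b]
    if (length(ups)) {
      w <- meta$end_drainage_km2[match(ups, meta$branch_id)]
      xs <- c(0, xs); vs <- c(sum(end_val[ups] * w) / sum(w), vs)
    }
    o <- order(xs)
    rr <- reaches[reaches$branch_id == b, , drop = FALSE]
    vals[rr$reach_id] <- stats::approx(xs[o], vs[o], xout = rr$midpoint_m,
                                       rule = 2, ties = mean)$y
    end_val[b] <- stats::approx(xs[o], vs[o], xout = len_b, rule = 2,
                                ties = mean)$y
  }
  vals
}

#' Generate concentration surveys, anchor series and the true field
#'
#' The true field is separable: conc(reach, t) = R_gas(reach) * G_gas(t).
#' The static spatial pattern R is defined by lognormal values at the 20
#' survey nodes (CH4 far more variable than CO2), linearly interpolated
#' along the network; the temporal signal G is an AR(1) lognormal series -
#' piecewise linear between biweekly knots for CH4 (matching the manual
#' sampling cadence) and daily for CO2 (matching sensor daily means).
#' Surveys observe the field at the nodes on 5 (CH4) / 7 (CO2) dates in the
#' second year, anchors observe it at 4 stations at their native cadence;
#' all observations carry multiplicative lognormal noise (`conc_noise_sdlog`,
#' zero in a noiseless scenario).
#'
#' @param sc A [catchment_scenario()].
#' @param network Output of [gen_network()].
#' @param reaches Reach table from [discretize()].
#' @return List with `points`, `surveys`, `anchor_points`, `anchors`,
#'   `truth` (reach_id, date, gas, conc).
#' @export
gen_concentrations <- function(sc, network, reaches) {
  set.seed(sc$seed + 4L)
  dates <- .scenario_dates(sc)
  topology <- network$topology
  lens <- sc$branch_lengths

  # survey nodes: allocated to branches proportionally to length
  n_pts <- pmax(1, round(sc$n_survey_points * lens / sum(lens)))
  names(n_pts) <- names(lens)
  while (sum(n_pts) > sc$n_survey_points) n_pts[which.max(n_pts)] <-
    n_pts[which.max(n_pts)] - 1
  while (sum(n_pts) < sc$n_survey_points) n_pts[which.min(n_pts)] <-
    n_pts[which.min(n_pts)] + 1
  points <- do.call(rbind, lapply(names(lens), function(b) {
    k <- n_pts[[b]]
    x <- (seq_len(k) - 0.5) / k * lens[[b]] +
      stats::runif(k, -0.04, 0.04) * lens[[b]] / k
    data.frame(branch_id = b, distance_m = pmin(pmax(x, 1), lens[[b]] - 1),
               stringsAsFactors = FALSE)
  }))
  points$point_id <- sprintf("P%02d", seq_len(nrow(points)))
  # anchors: most-downstream node on each designated branch
  anchor_rows <- vapply(sc$anchor_branches, function(b) {
    idx <- which(points$branch_id == b)
    idx[which.max(points$distance_m[idx])]
  }, integer(1))
  points$is_anchor <- seq_len(nrow(points)) %in% anchor_rows

  # static spatial pattern R at the nodes (mean 1 on the natural scale)
  points$r_ch4 <- exp(stats::rnorm(nrow(points), -sc$ch4_spatial_sdlog^2 / 2,
                                   sc$ch4_spatial_sdlog))
  points$r_co2 <- exp(stats::rnorm(nrow(points), -sc$co2_spatial_sdlog^2 / 2,
                                   sc$co2_spatial_sdlog))

  # temporal signals
  knots <- seq(min(dates), max(dates), by = sc$ch4_cadence_d)
  g_ch4_knots <- sc$ch4_level_um *
    exp(.ar1(length(knots), sc$ch4_anchor_ar[["phi"]],
             sc$ch4_anchor_ar[["sd"]]))
  g_ch4 <- stats::approx(as.numeric(knots), g_ch4_knots,
                         xout = as.numeric(dates), rule = 2)$y
  g_co2 <- sc$co2_level_um *
    exp(.ar1(length(dates), sc$co2_anchor_ar[["phi"]],
             sc$co2_anchor_ar[["sd"]]))

  # true per-reach spatial pattern by independent interpolation
  nodes_ch4 <- data.frame(branch_id = points$branch_id,
                          distance_m = points$distance_m,
                          value = points$r_ch4)
  nodes_co2 <- data.frame(branch_id = points$branch_id,
                          distance_m = points$distance_m,
                          value = points$r_co2)
  r_ch4_reach <- .truth_spatial(nodes_ch4, reaches, topology)
  r_co2_reach <- .truth_spatial(nodes_co2, reaches, topology)

  truth <- rbind(
    data.frame(reach_id = rep(names(r_ch4_reach), each = length(dates)),
               date = rep(dates, length(r_ch4_reach)), gas = "CH4",
               conc = rep(unname(r_ch4_reach), each = length(dates)) *
                 rep(g_ch4, length(r_ch4_reach)),
               stringsAsFactors = FALSE),
    data.frame(reach_id = rep(names(r_co2_reach), each = length(dates)),
               date = rep(dates, length(r_co2_reach)), gas = "CO2",
               conc = rep(unname(r_co2_reach), each = length(dates)) *
                 rep(g_co2, length(r_co2_reach)),
               stringsAsFactors = FALSE)
  )

  # survey dates: CH4 on biweekly knots in the second year, CO2 on evenly
  # spread second-year dates
  yr2 <- format(dates, "%Y") == format(max(dates), "%Y")
  knots_yr2 <- knots[format(knots, "%Y") == format(max(dates), "%Y") &
                       knots >= min(dates[yr2]) + 90 &
                       knots <= max(dates) - 60]
  ch4_dates <- knots_yr2[round(seq(1, length(knots_yr2),
                                   length.out = sc$n_ch4_surveys))]
  co2_dates <- dates[yr2][round(seq(100, sum(yr2) - 60,
                                    length.out = sc$n_co2_surveys))]

  noise <- function(n) exp(stats::rnorm(n, 0, sc$conc_noise_sdlog))
  surveys <- rbind(
    do.call(rbind, lapply(ch4_dates, function(d) {
      g <- g_ch4[match(d, dates)]
      data.frame(gas = "CH4", date = d, point_id = points$point_id,
                 branch_id = points$branch_id,
                 distance_m = points$distance_m,
                 conc = points$r_ch4 * g * noise(nrow(points)),
                 stringsAsFactors = FALSE)
    })),
    do.call(rbind, lapply(co2_dates, function(d) {
      g <- g_co2[match(d, dates)]
      data.frame(gas = "CO2", date = d, point_id = points$point_id,
                 branch_id = points$branch_id,
                 distance_m = points$distance_m,
                 conc = points$r_co2 * g * noise(nrow(points)),
                 stringsAsFactors = FALSE)
    }))
  )

  ap <- points[points$is_anchor, , drop = FALSE]
  anchor_points <- data.frame(anchor_id = ap$point_id,
                              branch_id = ap$branch_id,
                              distance_m = ap$distance_m,
                              stringsAsFactors = FALSE)
  anchors <- rbind(
    do.call(rbind, lapply(seq_len(nrow(ap)), function(i) {
      data.frame(gas = "CH4", date = knots, anchor_id = ap$point_id[i],
                 conc = ap$r_ch4[i] *
                   stats::approx(as.numeric(dates), g_ch4,
                                 xout = as.numeric(knots))$y *
                   noise(length(knots)),
                 stringsAsFactors = FALSE)
    })),
    do.call(rbind, lapply(seq_len(nrow(ap)), function(i) {
      data.frame(gas = "CO2", date = dates, anchor_id = ap$point_id[i],
                 conc = ap$r_co2[i] * g_co2 * noise(length(dates)),
                 stringsAsFactors = FALSE)
    }))
  )
  list(points = points, surveys = surveys, anchor_points = anchor_points,
       anchors = anchors, truth = truth,
       spatial_truth = list(CH4 = r_ch4_reach, CO2 = r_co2_reach))
}

#' Forward-simulate one tracer injection
#'
#' Inverse of the estimation chain: from a known true k600, the propane loss
#' rate at the run's temperature and depth is rate = k_propane / (1440 *
#' depth); the downstream relative concentration combines first-order loss
#' with groundwater dilution, c_down = c_up * exp(-rate * tau) *
#' (q_up / q_down), with (q_up, q_down) from [split_discharge()].
#'
#' @param length_m,depth_m,slope_pct Reach geometry.
#' @param velocity_ms True water velocity (sets tau = length / 60 v).
#' @param true_k600 True k600 (m d^-1).
#' @param water_temp_c Water temperature (degC).
#' @param gw_fraction Relative groundwater discharge gain over the reach.
#' @param q_mean_Ls Mean reach discharge (L s^-1).
#' @param c_up Upstream relative tracer concentration (arbitrary units).
#' @return One-row data frame in the injection-table schema plus
#'   `true_k600` and `true_velocity_ms`.
#' @export
simulate_injection <- function(length_m, depth_m, slope_pct, velocity_ms,
                               true_k600, water_temp_c, gw_fraction,
                               q_mean_Ls, c_up = 100) {
  tau <- length_m / (60 * velocity_ms)
  k_prop <- k_gas_from_k600(true_k600, schmidt_number("C3H8", water_temp_c))
  rate <- k_prop / (1440 * depth_m)
  qs <- split_discharge(q_mean_Ls, gw_fraction)
  c_down <- c_up * exp(-rate * tau) * qs[["q_up"]] / qs[["q_down"]]
  data.frame(length_m = length_m, depth_m = depth_m, slope_pct = slope_pct,
             travel_time_min = tau, c_up = c_up, c_down = c_down,
             q_mean_Ls = q_mean_Ls, q_diff_pct = gw_fraction * 100,
             water_temp_C = water_temp_c, true_k600 = true_k600,
             true_velocity_ms = velocity_ms)
}

#' Generate a tracer-injection campaign
#'
#' Samples reach-days from three near-flat and three steep end-member
#' reaches (excluding ice periods and above-cap velocities, where injections
#' are not feasible) and forward-simulates each injection from the true
#' hydraulics via [simulate_injection()]. Injected sub-reach lengths are
#' capped at ~30 m as in field practice; depth follows the scenario's
#' depth-area power law.
#'
#' @param sc A [catchment_scenario()].
#' @param reaches Reach table from [discretize()].
#' @param hydraulics Truth table from [gen_hydraulics()].
#' @param discharge Output of [gen_discharge()] (for water temperature and
#'   the ice mask).
#' @return Data frame: injection-table schema plus `reach_id`, `date` and
#'   the true k600/velocity columns.
#' @export
gen_injections <- function(sc, reaches, hydraulics, discharge) {
  set.seed(sc$seed + 5L)
  ice <- ice_mask(discharge$air_temp, sc$ice_min_run)
  open_dates <- ice$date[!ice$excluded]
  flat <- reaches[order(reaches$slope_pct), ]
  flat <- flat[flat$length_m >= 20, ][1:3, ]
  steep <- reaches[order(-reaches$slope_pct), ][1:3, ]
  sel <- rbind(flat, steep)
  cand <- hydraulics[hydraulics$reach_id %in% sel$reach_id &
                       hydraulics$date %in% open_dates &
                       hydraulics$velocity_ms <= 0.95 * sc$v_cap, ]
  cand <- merge(cand, sel[, c("reach_id", "length_m", "slope_pct",
                              "drainage_km2")], by = "reach_id")
  idx <- sample.int(nrow(cand), min(sc$n_injection_runs, nrow(cand)))
  wt <- discharge$water_temp
  runs <- lapply(idx, function(i) {
    r <- cand[i, ]
    depth <- sc$depth_coef * r$drainage_km2^sc$depth_exp
    inj <- simulate_injection(
      length_m = min(r$length_m, 30), depth_m = depth,
      slope_pct = r$slope_pct, velocity_ms = r$velocity_ms,
      true_k600 = r$k600_md,
      water_temp_c = wt$water_temp_C[match(r$date, wt$date)],
      gw_fraction = stats::runif(1, sc$gw_fraction_range[1],
                                 sc$gw_fraction_range[2]),
      q_mean_Ls = r$discharge_Ls, c_up = sc$injection_c_up)
    cbind(data.frame(reach_id = r$reach_id, date = r$date,
                     stringsAsFactors = FALSE), inj)
  })
  out <- do.call(rbind, runs)
  rownames(out) <- NULL
  out
}

#' Generate a high-frequency sensor series with condensation spikes
#'
#' Half-hourly CO2 sensor record: a smooth diel + seasonal base with mild
#' noise, plus injected condensation spikes (isolated values 1.3-3x the
#' local level) whose indices are returned as ground truth for despiking
#' tests.
#'
#' @param sc A [catchment_scenario()].
#' @param n_days Length of the record (days, default 20).
#' @param n_spikes Number of injected spikes (default 15).
#' @return List with `series` (time, value) and `spike_idx`.
#' @export
gen_sensor_series <- function(sc, n_days = 20, n_spikes = 15) {
  set.seed(sc$seed + 6L)
  t_h <- seq(0, n_days * 24, by = 0.5)
  base <- 2000 + 300 * sin(2 * pi * t_h / 24) + 150 * sin(2 * pi * t_h / 240)
  value <- base * exp(stats::rnorm(length(t_h), 0, 0.01))
  spike_idx <- sort(sample(seq(25, length(t_h) - 25), n_spikes))
  value[spike_idx] <- value[spike_idx] *
    stats::runif(n_spikes, 1.3, 3)
  list(series = data.frame(time = t_h, value = value), spike_idx = spike_idx)
}

#' Generate a complete synthetic catchment dataset
#'
#' Runs all generators in a fixed order and bundles their outputs together
#' with the discretised reach table the truth refers to. Every element is a
#' deterministic function of the scenario seed.
#'
#' @param sc A [catchment_scenario()].
#' @return List: `scenario`, `network`, `reaches`, `discharge`,
#'   `hydraulics`, `conc`, `injections`.
#' @export
gen_catchment_dataset <- function(sc = catchment_scenario()) {
  network <- gen_network(sc)
  reaches <- discretize(network$profile, sc$dz)
  discharge <- gen_discharge(sc, network)
  hydraulics <- gen_hydraulics(sc, reaches, discharge$daily)
  conc <- gen_concentrations(sc, network, reaches)
  injections <- gen_injections(sc, reaches, hydraulics, discharge)
  list(scenario = sc, network = network, reaches = reaches,
       discharge = discharge, hydraulics = hydraulics, conc = conc,
       injections = injections)
}

# brute-force run-length scan marking days inside >min_run sub-zero runs;
# written independently of ice_mask() so it can serve as its oracle
.brute_ice <- function(air_temp, min_run = 3) {
  a <- air_temp[order(air_temp$date), , drop = FALSE]
  n <- nrow(a)
  excl <- logical(n)
  for (i in seq_len(n)) {
    if (a$air_temp_C[i] >= 0) next
    lo <- i; hi <- i
    while (lo > 1 && a$air_temp_C[lo - 1] < 0) lo <- lo - 1
    while (hi < n && a$air_temp_C[hi + 1] < 0) hi <- hi + 1
    excl[i] <- (hi - lo + 1) > min_run
  }
  a$excluded <- excl
  a
}

#' True emissions of a synthetic dataset
#'
#' Computes the generator-truth reach-day fluxes and annual totals by direct
#' composition of the gas-physics operations on the true hydraulics and
#' concentration field (ice days excluded by an independent run-length
#' scan). Used as the reference against which the full pipeline's totals
#' are checked.
#'
#' @param dataset Output of [gen_catchment_dataset()].
#' @return List with `states` (reach-day truth incl. fluxes and masses) and
#'   `annual` (per-year totals: ch4_kg, co2_mg).
#' @export
truth_emissions <- function(dataset) {
  sc <- dataset$scenario
  reaches <- dataset$reaches
  hyd <- dataset$hydraulics
  wt <- dataset$discharge$water_temp
  ice <- .brute_ice(dataset$discharge$air_temp, sc$ice_min_run)

  tr <- dataset$conc$truth
  ch4 <- tr[tr$gas == "CH4", c("reach_id", "date", "conc")]
  co2 <- tr[tr$gas == "CO2", c("reach_id", "date", "conc")]
  names(ch4)[3] <- "conc_CH4"; names(co2)[3] <- "conc_CO2"
  st <- merge(hyd, ch4, by = c("reach_id", "date"))
  st <- merge(st, co2, by = c("reach_id", "date"))
  st$water_temp_C <- wt$water_temp_C[match(st$date, wt$date)]
  st$excluded <- ice$excluded[match(st$date, ice$date)]
  area <- reaches$area_m2[match(st$reach_id, reaches$reach_id)]

  e_ch4 <- reach_day_emission(st$k600_md, st$water_temp_C, st$conc_CH4,
                              sc$atm_ch4_ppm, "CH4", area)
  e_co2 <- reach_day_emission(st$k600_md, st$water_temp_C, st$conc_CO2,
                              sc$atm_co2_ppm, "CO2", area)
  st$flux_CH4 <- e_ch4$flux_mmol_m2_d
  st$flux_CO2 <- e_co2$flux_mmol_m2_d
  st$mass_CH4_kg <- e_ch4$mass_kg_d
  st$mass_CO2_kg <- e_co2$mass_kg_d

  ok <- !st$excluded
  yr <- format(as.Date(st$date[ok]), "%Y")
  annual <- data.frame(
    year = sort(unique(yr)),
    ch4_kg = as.numeric(tapply(st$mass_CH4_kg[ok], yr, sum)),
    co2_mg = as.numeric(tapply(st$mass_CO2_kg[ok], yr, sum)) / 1000)
  list(states = st, annual = annual)
}
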
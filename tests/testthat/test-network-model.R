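test_that("discretisation yields fixed-drop reaches and conserves geometry", {
  # uniform 2 m drop over 400 m -> four 100 m reaches of slope 0.5 %
  prof <- data.frame(branch_id = "B", distance_m = seq(0, 400, 20),
                     elevation_m = 60 - seq(0, 400, 20) * 2 / 400,
                     drainage_km2 = 0.5, width_m = 1)
  r <- discretize(prof, dz = 0.5)
  expect_equal(nrow(r), 4)
  expect_equal(r$length_m, rep(100, 4))
  expect_equal(r$slope_pct, rep(0.5, 4))
  expect_equal(as.character(r$slope_category), rep("S1", 4))

  # single steep segment: 0.5 m over 2.6 m -> 19.2 %, category S5
  prof2 <- data.frame(branch_id = "S", distance_m = c(0, 2.6),
                      elevation_m = c(10, 9.5), drainage_km2 = 0.2)
  r2 <- discretize(prof2)
  expect_equal(r2$slope_pct, 100 * 0.5 / 2.6)
  expect_equal(as.character(r2$slope_category), "S5")

  # a branch with total drop below dz still yields one reach
  prof3 <- data.frame(branch_id = "F", distance_m = c(0, 100),
                      elevation_m = c(10, 9.9), drainage_km2 = 1)
  expect_equal(nrow(discretize(prof3)), 1)

  # local rises are flattened with a warning
  prof4 <- data.frame(branch_id = "R", distance_m = c(0, 50, 100, 150),
                      elevation_m = c(10, 9.4, 9.6, 8.9), drainage_km2 = 1)
  expect_warning(r4 <- discretize(prof4), "flattened")
  expect_equal(sum(r4$drop_m), 10 - 8.9)
})

test_that("discretisation covers each branch exactly (generated network)", {
  ds <- sg_ds_noiseless()
  prof <- ds$network$profile
  r <- ds$reaches
  for (b in unique(prof$branch_id)) {
    pb <- prof[prof$branch_id == b, ]
    rb <- r[r$branch_id == b, ]
    expect_equal(sum(rb$length_m), max(pb$distance_m))
    expect_equal(sum(rb$drop_m), max(pb$elevation_m) - min(pb$elevation_m))
    # contiguous coverage
    expect_equal(rb$start_m[-1], rb$end_m[-nrow(rb)])
  }
  # steeper reaches are shorter on average
  expect_gt(mean(r$length_m[r$slope_category == "S1"]),
            5 * mean(r$length_m[r$slope_category == "S5"]))
})

test_that("slope categories use lower-inclusive boundaries", {
  expect_equal(as.character(slope_category(c(0, 0.5, 1, 2, 4, 6, 19.3, 21))),
               c("S1", "S1", "S2", "S3", "S4", "S5", "S5", "S5"))
  expect_error(slope_category(-0.1), "non-negative")
})

test_that("daily D = bA scaling is exact on proportional data and errors on one station", {
  st <- data.frame(station_id = c("a", "b", "c"),
                   date = as.Date("2013-06-01"),
                   q_Ls = 3 * c(1, 2, 5), drainage_km2 = c(1, 2, 5))
  sc <- fit_daily_scaling(st)
  expect_equal(sc$b, 3)
  expect_equal(sc$r2, 1)
  expect_equal(sc$n_stations, 3)
  expect_error(fit_daily_scaling(st[1, ]), "2 stations")
  expect_equal(reach_discharge(2, 10), 20)
  expect_equal(reach_discharge(4, 10), 2 * reach_discharge(2, 10))
})

test_that("scaling recovery from the noisy stations matches the generator truth", {
  ds <- sg_ds_noisy()
  sc <- fit_daily_scaling(ds$discharge$stations)
  rel <- abs(sc$b - ds$discharge$daily$b_true) / ds$discharge$daily$b_true
  expect_lt(stats::median(rel), 0.04)
  expect_gt(mean(rel < 0.10), 0.95)
  expect_gt(min(sc$r2), 0.97)
})

test_that("velocity predictions evaluate the printed model and respect the smearing factor", {
  expect_equal(newman_factor(0), 1)
  expect_equal(newman_factor(0.05), exp(0.05 * log(10)^2 / 2))

  v <- predict_velocity(82.8, 7.5, bias_correct = FALSE)
  expect_equal(v, 10^(-1.323 + 0.466 * log10(82.8) + 0.056 * log10(7.5)))
  expect_equal(round(v, 3), 0.417)
  expect_equal(predict_velocity(82.8, 7.5),
               v * newman_factor(velocity_model()$mse))
  # monotone in discharge and slope
  expect_gt(predict_velocity(100, 5), predict_velocity(50, 5))
  expect_gt(predict_velocity(50, 10), predict_velocity(50, 5))
  expect_error(predict_velocity(0, 5), "positive")
})

test_that("k600 predictions evaluate the printed model, calibration and velocity cap", {
  k <- predict_k600(0.3, 7.5, bias_correct = FALSE)
  expect_equal(k, 0.89 * 10^(0.319 + 2.110 * 0.3 + 1.026 * log10(7.5)))
  expect_equal(round(k, 1), 63.0)
  m0 <- k600_model(mse = 0)
  expect_equal(predict_k600(0, 1, m0, calibration = 1), 10^0.319)
  # above the cap the reach maximum wins over extrapolation
  k_cap <- predict_k600(0.7, 5)
  expect_equal(predict_k600(0.9, 5, reach_max = 123), 123)
  expect_warning(k_over <- predict_k600(0.9, 5), "cap")
  expect_equal(k_over, k_cap)
  # monotone below the cap
  expect_gt(predict_k600(0.5, 5), predict_k600(0.3, 5))
  expect_gt(predict_k600(0.3, 10), predict_k600(0.3, 5))
})

test_that("model fitting recovers a noiseless synthetic world exactly", {
  set.seed(42)
  n <- 40
  # discharge range kept below the level where modelled velocities would hit
  # the 0.7 m s^-1 cap, so the calibration self-consistency check is clean
  d <- 10^runif(n, 0.5, 2.2)
  s <- 10^runif(n, log10(0.3), log10(19))
  v <- 10^(-1.323 + 0.466 * log10(d) + 0.056 * log10(s))
  k6 <- 10^(0.319 + 2.110 * v + 1.026 * log10(s))
  dat <- data.frame(velocity_ms = v, discharge_Ls = d, slope_pct = s,
                    k600_md = k6)
  suppressWarnings({
    vm <- fit_velocity_model(dat)
    km <- fit_k600_model(dat)
  })
  expect_equal(unname(vm$coefficients), c(-1.323, 0.466, 0.056),
               tolerance = 1e-9)
  expect_equal(unname(km$coefficients), c(0.319, 2.110, 1.026),
               tolerance = 1e-9)
  expect_equal(vm$adj_r2, 1, tolerance = 1e-9)
  expect_lt(vm$mse, 1e-12)
  expect_equal(vm$n, n)

  # self-consistency: an unbiased model gives calibration ~ 1
  modelled <- predict_k600(v, s, km, calibration = 1, bias_correct = TRUE)
  expect_equal(calibration_factor(k6, modelled), 1, tolerance = 1e-9)
})

test_that("model fitting rejects degenerate designs", {
  dat <- data.frame(velocity_ms = rep(0.2, 12), discharge_Ls = 1:12,
                    slope_pct = rep(0.5, 12), k600_md = rep(2, 12))
  expect_error(fit_k600_model(dat), "slope category")
  # collinear log10 D and log10 S -> rank deficient
  d <- 10^seq(0, 1, length.out = 12)
  dat2 <- data.frame(velocity_ms = d, discharge_Ls = d, slope_pct = d,
                     k600_md = d)
  expect_error(fit_velocity_model(dat2), "rank deficient")
  expect_error(fit_velocity_model(dat2[1:5, ]), ">= 10")
})

test_that("calibration factor matches its closed form", {
  expect_equal(calibration_factor(1:10, 1:10), 1)
  expect_equal(calibration_factor(1:10, 2 * (1:10)), 0.5)
  set.seed(3)
  meas <- runif(30, 1, 100)
  modl <- meas * exp(rnorm(30, 0, 0.3))
  expect_equal(calibration_factor(meas, modl),
               sum(meas * modl) / sum(modl^2))
  # with an intercept the estimate differs but stays positive
  expect_gt(calibration_factor(meas, modl, intercept = TRUE), 0)
})

test_that("the ice mask matches a brute-force run-length scan", {
  d <- seq(as.Date("2013-01-01"), by = "day", length.out = 60)
  at <- data.frame(date = d, air_temp_C = rep(5, 60))
  expect_false(any(ice_mask(at)$excluded))

  at$air_temp_C[10:14] <- -2                       # 5-day run -> excluded
  at$air_temp_C[30:32] <- -1                       # 3-day run -> kept
  m <- ice_mask(at)
  expect_true(all(m$excluded[10:14]))
  expect_false(any(m$excluded[30:32]))

  # random series vs an independent scan
  set.seed(99)
  at$air_temp_C <- rnorm(60, 0, 3)
  m <- ice_mask(at)
  brute <- logical(60)
  i <- 1
  while (i <= 60) {
    if (at$air_temp_C[i] < 0) {
      j <- i
      while (j < 60 && at$air_temp_C[j + 1] < 0) j <- j + 1
      if (j - i + 1 > 3) brute[i:j] <- TRUE
      i <- j + 1
    } else i <- i + 1
  }
  expect_equal(m$excluded, brute)
})
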
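test_that("discharge splitting preserves the mean and the stated difference", {
  expect_equal(split_discharge(100, 0), c(q_up = 100, q_down = 100))
  qs <- split_discharge(100, 0.005)
  expect_equal(mean(qs), 100)
  expect_equal((qs[["q_down"]] - qs[["q_up"]]) / 100, 0.005)
  set.seed(1)
  for (i in 1:20) {
    mq <- runif(1, 1, 300); f <- runif(1, 0, 0.05)
    qs <- split_discharge(mq, f)
    expect_equal(mean(qs), mq)
    expect_gte(qs[["q_down"]], qs[["q_up"]])
  }
  expect_error(split_discharge(-1, 0), "positive")
  expect_error(split_discharge(10, 0.2), "0.05")
})

test_that("dilution-corrected rate has its closed forms and flags tracer gain", {
  expect_equal(dilution_corrected_rate(5, 10, 10, 50, 50), 0)
  expect_equal(dilution_corrected_rate(1, exp(1), 1, 50, 50), 1.0)
  # reduces to the uncorrected rate when discharge is constant
  expect_equal(dilution_corrected_rate(3.2, 87, 41, 20, 20),
               log(87 / 41) / 3.2)
  expect_warning(dilution_corrected_rate(5, 10, 11, 50, 50), "negative")
  expect_error(dilution_corrected_rate(5, -1, 1, 50, 50), "positive")
  expect_error(dilution_corrected_rate(0, 1, 1, 50, 50), "positive")
})

test_that("k600 from an injection is invariant to the tracer concentration scale", {
  k1 <- injection_to_k600(3.4, 100, 60, 27.5, 27.6, 0.15, 9.2)
  k2 <- injection_to_k600(3.4, 100 * 37.2, 60 * 37.2, 27.5, 27.6, 0.15, 9.2)
  expect_equal(k1, k2)
  expect_equal(injection_to_k600(3.4, 80, 80, 30, 30, 0.15, 9.2), 0)
})

test_that("rate-to-k conversion and travel-time velocities are exact arithmetic", {
  expect_equal(rate_to_k(0.01, 0.2), 2.88)
  expect_equal(rate_to_k(0, 0.3), 0)
  expect_equal(round(velocity_from_travel_time(31, 3.9), 1), 0.1)
  expect_equal(round(velocity_from_travel_time(24, 3.2), 1), 0.1)
  expect_equal(velocity_from_travel_time(24, 3.2), 0.125)
  # inverse round trip
  v <- velocity_from_travel_time(50, 4)
  expect_equal(50 / (60 * v), 4)
  expect_error(velocity_from_travel_time(10, 0), "positive")
})

test_that("forward-simulated injections recover the true k600", {
  # single run with known truth, including groundwater dilution
  run <- simulate_injection(length_m = 30, depth_m = 0.15, slope_pct = 7.5,
                            velocity_ms = 0.3, true_k600 = 80,
                            water_temp_c = 9, gw_fraction = 0.005,
                            q_mean_Ls = 80)
  qs <- split_discharge(run$q_mean_Ls, run$q_diff_pct / 100)
  k600 <- injection_to_k600(run$travel_time_min, run$c_up, run$c_down,
                            qs[["q_up"]], qs[["q_down"]], run$depth_m,
                            run$water_temp_C)
  expect_lt(abs(k600 - 80) / 80, 0.01)

  # zero-loss, zero-inflow run is the identity
  r0 <- simulate_injection(30, 0.15, 7.5, 0.3, 0, 9, 0, 80)
  expect_equal(r0$c_down, r0$c_up)

  # the whole campaign of the noisy world
  ds <- sg_ds_noisy()
  inj <- injections_k600(ds$injections)
  expect_lt(max(abs(inj$k600_md - ds$injections$true_k600) /
                  ds$injections$true_k600), 0.01)
  expect_equal(inj$velocity_ms, ds$injections$true_velocity_ms)
})

test_that("flux-based k agrees with the dilution-corrected route", {
  # hand-computed single run: equal discharge, halving concentration,
  # tau = 2 min, depth 0.2 m -> k = 1440 * 0.2 * ln 2 / 2
  k_flux <- flux_based_k(2, 100, 50, 30, 30, 0.2)
  expect_equal(k_flux, 1440 * 0.2 * log(2) / 2, tolerance = 1e-12)
  expect_equal(flux_based_k(2, 80, 80, 30, 30, 0.2), 0)

  # oracle equivalence across the simulated campaign
  ds <- sg_ds_noisy()
  inj <- injections_k600(ds$injections)
  k_alt <- flux_based_k(inj$travel_time_min, inj$c_up, inj$c_down,
                        inj$q_up_Ls, inj$q_down_Ls, inj$depth_m)
  expect_lt(max(abs(k_alt - inj$k_md) / inj$k_md), 0.02)
})

test_that("steep reaches yield far higher k600 than flat reaches", {
  ds <- sg_ds_noisy()
  inj <- injections_k600(ds$injections)
  steep <- inj$slope_pct >= 6
  expect_gt(mean(inj$k600_md[steep]), 5 * mean(inj$k600_md[!steep]))
  # plausibility envelope of measured k600 in this kind of system
  expect_true(all(inj$k600_md > 0.1 & inj$k600_md < 600))
})

test_that("the injection table schema is validated", {
  expect_error(injections_k600(data.frame(reach_id = "a")), "missing column")
})
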
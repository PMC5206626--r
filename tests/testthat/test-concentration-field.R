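test_that("despiking removes isolated deviations and leaves smooth series alone", {
  const <- data.frame(time = seq(0, 100, 0.5), value = 500)
  expect_equal(nrow(despike_sensor(const)), nrow(const))

  spiked <- const
  spiked$value[100] <- 750                       # 1.5x an otherwise flat series
  out <- despike_sensor(spiked)
  expect_equal(attr(out, "n_removed"), 1L)
  expect_false(750 %in% out$value)

  # endpoint uses the single available window
  spiked2 <- const
  spiked2$value[1] <- 900
  expect_equal(attr(despike_sensor(spiked2), "n_removed"), 1L)

  expect_equal(nrow(despike_sensor(const[0, ])), 0)
  expect_error(despike_sensor(data.frame(time = c(1, 1), value = c(1, 2))),
               "strictly increasing")
})

test_that("despiking equals a brute-force windowed scan and is idempotent", {
  sensor <- gen_sensor_series(catchment_scenario(seed = 5))
  s <- sensor$series

  # independent brute-force scan of the 20 %-of-both-windows rule
  tt <- s$time; v <- s$value
  brute_remove <- vapply(seq_along(v), function(i) {
    b <- v[tt >= tt[i] - 12 & tt < tt[i]]
    a <- v[tt > tt[i] & tt <= tt[i] + 12]
    db <- length(b) > 0 && abs(v[i] - mean(b)) > 0.2 * mean(b)
    da <- length(a) > 0 && abs(v[i] - mean(a)) > 0.2 * mean(a)
    if (length(b) && length(a)) db && da else if (length(b)) db else da
  }, logical(1))

  out <- despike_sensor(s)
  expect_equal(out$time, s$time[!brute_remove])
  expect_equal(attr(out, "n_removed"), sum(brute_remove))
  # all injected condensation spikes are caught
  expect_true(all(sensor$spike_idx %in% which(brute_remove)))
  # idempotent on its own output
  out2 <- despike_sensor(out)
  expect_equal(out2$value, out$value)
})

test_that("spatial interpolation is linear along a branch with constant extrapolation", {
  prof <- data.frame(branch_id = "B", distance_m = seq(0, 1000, 100),
                     elevation_m = 60 - seq(0, 1000, 100) * 0.004,
                     drainage_km2 = 1, width_m = 1)
  reaches <- discretize(prof)
  topo <- data.frame(branch_id = "B", downstream_id = NA)

  sv_eq <- data.frame(branch_id = "B", distance_m = c(0, 1000),
                      conc = c(10, 10))
  expect_true(all(spatial_interpolate(sv_eq, reaches, topo)$conc == 10))

  sv <- data.frame(branch_id = "B", distance_m = c(0, 1000), conc = c(10, 20))
  out <- spatial_interpolate(sv, reaches, topo)
  mid <- reaches$midpoint_m[which.min(abs(reaches$midpoint_m - 500))]
  expect_equal(out$conc[reaches$midpoint_m == mid], 10 + 10 * mid / 1000)
  # bounded by the sample range on an unbranched segment
  expect_true(all(out$conc >= 10 & out$conc <= 20))

  # single interior sample -> constant on both sides
  sv1 <- data.frame(branch_id = "B", distance_m = 400, conc = 12)
  expect_true(all(spatial_interpolate(sv1, reaches, topo)$conc == 12))
  expect_error(spatial_interpolate(sv[0, ], reaches, topo), "no samples")
  expect_error(spatial_interpolate(transform(sv, conc = c(-1, 2)),
                                   reaches, topo), "positive")
})

test_that("confluences mix by drainage-weighted means (hand-computed oracle)", {
  reaches <- discretize(sg_toy_profile())
  topo <- sg_toy_topology()
  # one sample per tributary, two on the main stem
  sv <- data.frame(branch_id = c("T1", "T2", "M", "M"),
                   distance_m = c(1000, 500, 500, 1000),
                   conc = c(10, 30, 14, 18))
  out <- spatial_interpolate(sv, reaches, topo)
  # head of M: weighted mean of T1 (A = 1.0) and T2 (A = 0.5) endpoint values
  head_m <- (10 * 1.0 + 30 * 0.5) / 1.5
  rm_ <- reaches[reaches$branch_id == "M", ]
  got <- out$conc[match(rm_$reach_id, out$reach_id)]
  manual <- ifelse(rm_$midpoint_m <= 500,
                   head_m + (14 - head_m) * rm_$midpoint_m / 500,
                   14 + (18 - 14) * (rm_$midpoint_m - 500) / 500)
  expect_equal(got, manual)

  # tributary reaches: constant beyond their single terminal sample
  rt1 <- reaches[reaches$branch_id == "T1", ]
  expect_true(all(out$conc[match(rt1$reach_id, out$reach_id)] == 10))
})

test_that("unsampled headwater branches inherit from downstream with a warning", {
  reaches <- discretize(sg_toy_profile())
  topo <- sg_toy_topology()
  sv <- data.frame(branch_id = c("T1", "M"), distance_m = c(500, 500),
                   conc = c(10, 20))
  expect_warning(out <- spatial_interpolate(sv, reaches, topo), "inherit")
  rt2 <- reaches[reaches$branch_id == "T2", ]
  expect_true(all(is.finite(out$conc[match(rt2$reach_id, out$reach_id)])))
})

test_that("relative ratios recover a known multiplicative field", {
  # anchor-coincident reach: ratio 1, cv 0 across two identical surveys
  reaches <- discretize(sg_toy_profile())
  topo <- sg_toy_topology()
  dts <- as.Date(c("2014-06-01", "2014-07-01"))
  interp <- do.call(rbind, lapply(dts, function(d) {
    data.frame(date = d, reach_id = reaches$reach_id, conc = 10)
  }))
  anchors <- data.frame(date = rep(dts, 1), anchor_id = "A1", conc = 10)
  assignment <- data.frame(reach_id = reaches$reach_id, anchor_id = "A1")
  rr <- relative_ratios(interp, anchors, assignment)
  expect_true(all(rr$ratio == 1))
  expect_true(all(rr$cv == 0))
  expect_true(all(rr$n_surveys == 2))

  # the noiseless generated world: ratios equal the true spatial pattern
  ds <- sg_ds_noiseless()
  run <- sg_run_noiseless()
  rat <- run$ratios$CH4
  truth_r <- ds$conc$spatial_truth$CH4[rat$reach_id]
  anchor_r <- ds$conc$points$r_ch4[match(rat$anchor_id,
                                         ds$conc$points$point_id)]
  expect_equal(rat$ratio, unname(truth_r / anchor_r), tolerance = 1e-10)
  expect_lt(max(rat$cv), 1e-10)
})

test_that("temporal reconstruction gap-fills linearly and flags extrapolation", {
  dts <- seq(as.Date("2014-01-01"), by = "day", length.out = 30)
  anchors <- data.frame(date = as.Date(c("2014-01-05", "2014-01-19")),
                        anchor_id = "A1", conc = c(10, 24))
  ratios <- data.frame(reach_id = c("r1", "r2"), anchor_id = "A1",
                       ratio = c(1, 2))
  rec <- temporal_reconstruct(anchors, ratios, dts)
  r1 <- rec[rec$reach_id == "r1", ]
  expect_equal(r1$conc[r1$date == as.Date("2014-01-12")], 17)   # midpoint
  expect_equal(r1$conc[r1$date == as.Date("2014-01-05")], 10)
  expect_equal(r1$conc[r1$date == as.Date("2014-01-01")], 10)   # carried
  expect_true(r1$extrapolated[r1$date == as.Date("2014-01-01")])
  expect_false(any(r1$extrapolated[r1$date >= as.Date("2014-01-05") &
                                     r1$date <= as.Date("2014-01-19")]))
  r2 <- rec[rec$reach_id == "r2", ]
  expect_equal(r2$conc, 2 * r1$conc)
})

test_that("ratio-based reconstruction beats an anchor-only reconstruction", {
  ds <- sg_ds_noiseless()
  run <- sg_run_noiseless()
  truth <- ds$conc$truth
  tr_ch4 <- truth[truth$gas == "CH4", ]
  key <- paste(tr_ch4$reach_id, tr_ch4$date)

  st <- run$states
  got <- st$conc_CH4[match(key, paste(st$reach_id, st$date))]
  rmse_model <- sqrt(mean((got - tr_ch4$conc)^2, na.rm = TRUE))

  # anchor-only: every reach carries its anchor series unscaled (ratio 1)
  rat1 <- run$ratios$CH4
  rat1$ratio <- 1
  an <- ds$conc$anchors[ds$conc$anchors$gas == "CH4", ]
  rec1 <- temporal_reconstruct(an, rat1, unique(tr_ch4$date))
  got1 <- rec1$conc[match(key, paste(rec1$reach_id, rec1$date))]
  rmse_anchor <- sqrt(mean((got1 - tr_ch4$conc)^2, na.rm = TRUE))

  expect_lt(rmse_model, 1e-8)            # exact under the separable world
  expect_gt(rmse_anchor, 0.1)
})

test_that("uncertainty is the maximum ratio CV in percent", {
  expect_equal(uncertainty_pct(c(0, 0, 0)), 0)
  expect_equal(uncertainty_pct(c(0.1, 0.6, 0.25)), 60)
  expect_error(uncertainty_pct(numeric(0)), "no CVs")
})
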
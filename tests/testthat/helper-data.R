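# Shared fixtures, generated once per test run and cached. Two worlds:
# a noiseless scenario (pipeline must reproduce generator truth) and the
# default noisy scenario.

.sg_cache <- new.env(parent = emptyenv())

.sg_get <- function(key, fn) {
  if (is.null(.sg_cache[[key]])) assign(key, fn(), envir = .sg_cache)
  .sg_cache[[key]]
}

sg_ds_noiseless <- function() {
  .sg_get("ds0", function() {
    gen_catchment_dataset(catchment_scenario(seed = 7, noiseless = TRUE))
  })
}

sg_ds_noisy <- function() {
  .sg_get("ds1", function() {
    gen_catchment_dataset(catchment_scenario(seed = 11))
  })
}

sg_truth_noiseless <- function() {
  .sg_get("truth0", function() truth_emissions(sg_ds_noiseless()))
}

sg_inputs <- function(ds) {
  list(profile = ds$network$profile, topology = ds$network$topology,
       stations = ds$discharge$stations, air_temp = ds$discharge$air_temp,
       water_temp = ds$discharge$water_temp, injections = ds$injections,
       surveys = ds$conc$surveys, anchor_points = ds$conc$anchor_points,
       anchors = ds$conc$anchors)
}

sg_run_noiseless <- function() {
  .sg_get("run0", function() {
    suppressWarnings(run_emission_pipeline(sg_inputs(sg_ds_noiseless())))
  })
}

# simple two-tributary test network: T1 (0-1000 m) and T2 (0-500 m) join at
# the head of the main stem M (0-1000 m); mild uniform slopes
sg_toy_profile <- function() {
  mk <- function(b, L, el0, drop, a0, a1, n = 11) {
    x <- seq(0, L, length.out = n)
    data.frame(branch_id = b, distance_m = x,
               elevation_m = el0 - drop * x / L,
               drainage_km2 = a0 + (a1 - a0) * x / L,
               width_m = 1)
  }
  rbind(mk("T1", 1000, 60, 2, 0.1, 1.0),
        mk("T2", 500, 61, 3, 0.1, 0.5),
        mk("M", 1000, 58, 2, 1.5, 3.0))
}

sg_toy_topology <- function() {
  data.frame(branch_id = c("T1", "T2", "M"),
             downstream_id = c("M", "M", NA),
             stringsAsFactors = FALSE)
}
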
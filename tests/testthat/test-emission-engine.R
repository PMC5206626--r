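test_that("reach-day emissions compose the gas-physics chain exactly", {
  # at equilibrium concentration the flux and mass vanish
  c_eq <- equilibrium_concentration(405, 12, "CO2")
  e <- reach_day_emission(10, 12, c_eq, 405, "CO2", 500)
  expect_equal(e$flux_mmol_m2_d, 0)
  expect_equal(e$mass_kg_d, 0)

  # unit chain: k_gas = 1 m d^-1, gradient 1 uM, 1000 m^2 of CH4
  # -> 1000 mmol d^-1 = 16.04 g d^-1
  sc <- schmidt_number("CH4", 10)
  k600 <- k600_from_k(1, sc)
  c_eq <- equilibrium_concentration(2, 10, "CH4")
  e <- reach_day_emission(k600, 10, c_eq + 1, 2, "CH4", 1000)
  expect_equal(e$flux_mmol_m2_d, 1)
  expect_equal(e$mass_kg_d, 16.04 / 1000)

  # batch equals element-wise composition of the kernel operations
  set.seed(8)
  n <- 50
  k6 <- runif(n, 0.5, 200); tw <- runif(n, 1, 20)
  conc <- runif(n, 30, 800); area <- runif(n, 10, 400)
  e <- reach_day_emission(k6, tw, conc, 405, "CO2", area)
  manual_k <- k_gas_from_k600(k6, schmidt_number("CO2", tw))
  manual_f <- diffusive_flux(manual_k,
                             conc, equilibrium_concentration(405, tw, "CO2"))
  expect_equal(e$flux_mmol_m2_d, manual_f)
  expect_equal(e$mass_kg_d, manual_f * area * 44.01 / 1e6)
})

test_that("uncertainty bounds reproduce the printed ranges", {
  b <- uncertainty_bounds(8.8, 60)
  expect_equal(round(b[["low"]], 1), 3.5)
  expect_equal(uncertainty_bounds(1600, 25), c(low = 1200, high = 2000))
  expect_equal(uncertainty_bounds(7, 0), c(low = 7, high = 7))
  expect_error(uncertainty_bounds(1, -5), ">= 0")
})

test_that("discharge-ratio bins follow the boundary convention", {
  expect_equal(as.character(discharge_ratio_bin(c(10, 10), c(10, 10))),
               c("<1", "<1"))                      # ratio 1 -> first bin
  expect_equal(as.character(discharge_ratio_bin(45, 10)), ">4")
  expect_equal(as.character(discharge_ratio_bin(20, 10)), "2-3")
  expect_equal(as.character(discharge_ratio_bin(39.9, 10)), "3-4")
  # brute-force oracle on random ratios
  set.seed(21)
  q <- runif(200, 0, 60); mq <- 10
  r <- q / mq
  brute <- ifelse(r <= 1, "<1", ifelse(r < 2, "1-2", ifelse(r < 3, "2-3",
                  ifelse(r < 4, "3-4", ">4"))))
  expect_equal(as.character(discharge_ratio_bin(q, mq)), brute)
  expect_error(discharge_ratio_bin(1, 0), "positive")
})

test_that("category ratio tables are exact on a hand-computed toy", {
  reaches <- data.frame(reach_id = c("a", "b"),
                        slope_pct = c(0.5, 10),
                        slope_category = slope_category(c(0.5, 10)),
                        area_m2 = c(300, 100))
  states <- data.frame(reach_id = c("a", "b"), date = as.Date("2014-06-01"),
                       discharge_Ls = c(10, 10), k600_md = c(2, 20),
                       flux_CH4 = c(1, 3), flux_CO2 = c(100, 500),
                       excluded = FALSE)
  tab <- category_ratios(states, reaches, "slope_category")
  expect_equal(tab$percent[tab$category == "S1"], 75)
  expect_equal(sum(tab$percent, na.rm = TRUE), 100)
  expect_equal(tab$ch4_emission_ratio[tab$category == "S1"], 1 / 2)
  expect_equal(tab$ch4_emission_ratio[tab$category == "S5"], 3 / 2)
  expect_equal(tab$co2_emission_ratio[tab$category == "S5"], 500 / 300)
  expect_equal(tab$k_ratio[tab$category == "S5"], 20 / 11)

  # identical reaches -> all defined ratios are 1
  states2 <- states
  states2[, c("k600_md", "flux_CH4", "flux_CO2")] <- 1
  reaches2 <- reaches
  reaches2$slope_category <- slope_category(c(0.5, 0.5))
  tab2 <- category_ratios(states2, reaches2, "slope_category")
  expect_equal(tab2$ch4_emission_ratio[tab2$category == "S1"], 1)
})

test_that("mass-balance flux matches arithmetic and the k-based route on a steep reach", {
  expect_equal(mass_balance_flux(12, 50, 50, 30), 0)
  expect_equal(mass_balance_flux(10, 30, 20, 40), 216)
  expect_error(mass_balance_flux(1, 2, 1, 0), "positive")

  # synthetic steep section dominated by degassing: first-order loss along
  # the reach, compared with the k-based flux at the mean concentration
  h <- 0.1; v <- 0.3; w <- 1; len <- 30
  q <- v * w * h * 1000                      # L s^-1
  k600 <- 100
  k <- k_gas_from_k600(k600, schmidt_number("CO2", 10))
  c_eq <- equilibrium_concentration(405, 10, "CO2")
  tau_d <- len / v / 86400
  c_up <- 150
  c_down <- c_eq + (c_up - c_eq) * exp(-k * tau_d / h)
  f_mb <- mass_balance_flux(q, c_up, c_down, w * len)
  f_k <- diffusive_flux(k, (c_up + c_down) / 2, c_eq)
  expect_lt(abs(f_mb - f_k) / f_mb, 0.10)
})

test_that("aggregation conserves mass and is order-invariant", {
  one <- data.frame(reach_id = "a", date = as.Date("2014-06-01"),
                    discharge_Ls = 5, k600_md = 2, flux_CH4 = 1,
                    flux_CO2 = 10, mass_CH4_kg = 0.5, mass_CO2_kg = 40,
                    excluded = FALSE)
  reaches <- data.frame(reach_id = "a", slope_pct = 0.5,
                        slope_category = slope_category(0.5), area_m2 = 10)
  s <- aggregate_emissions(one, reaches, 60, 25)
  expect_equal(s$annual$ch4_kg, 0.5)
  expect_equal(s$annual$co2_mg, 0.04)

  tr <- sg_truth_noiseless()
  ds <- sg_ds_noiseless()
  s1 <- aggregate_emissions(tr$states, ds$reaches, 60, 25)
  shuffled <- tr$states[sample.int(nrow(tr$states)), ]
  s2 <- aggregate_emissions(shuffled, ds$reaches, 60, 25)
  expect_equal(s1$annual, s2$annual)
  # conservation: totals are exactly the sum of included reach-day masses
  ok <- !tr$states$excluded
  expect_equal(sum(s1$annual$ch4_kg), sum(tr$states$mass_CH4_kg[ok]))
  expect_equal(sum(s1$annual$co2_mg) * 1000, sum(tr$states$mass_CO2_kg[ok]))
  # bounds bracket the central value
  expect_lt(s1$mean_annual$ch4_bounds_kg[["low"]], s1$mean_annual$ch4_kg)
  expect_gt(s1$mean_annual$ch4_bounds_kg[["high"]], s1$mean_annual$ch4_kg)
})

test_that("network totals differ from mean-flux-times-area when flux and area correlate", {
  # steep reaches are small but emit intensely: the per-reach mass total and
  # the (unweighted mean areal flux) x (total area) estimator must diverge
  tr <- sg_truth_noiseless()
  ds <- sg_ds_noiseless()
  st <- tr$states[!tr$states$excluded, ]
  total_mass <- sum(st$mass_CO2_kg)
  area <- ds$reaches$area_m2[match(st$reach_id, ds$reaches$reach_id)]
  naive <- mean(st$flux_CO2) * sum(ds$reaches$area_m2) *
    length(unique(st$date)) * 44.01 / 1e6
  expect_gt(abs(naive - total_mass) / total_mass, 0.05)
})

test_that("the higher-discharge year has the higher mean k600", {
  ds <- sg_ds_noiseless()
  hyd <- ds$hydraulics
  yr <- format(as.Date(hyd$date), "%Y")
  q_by_year <- tapply(hyd$discharge_Ls, yr, mean)
  k_by_year <- tapply(hyd$k600_md, yr, mean)
  expect_equal(order(q_by_year), order(k_by_year))
})
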
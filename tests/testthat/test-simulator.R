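# Season engine: composition, modes, sweeps.

test_that("a soilless season with no Si source accumulates nothing", {
  sim <- run_simulation(short_config(si_water = 0, days = 5))
  expect_true(all(sim$trajectory$si_total == 0))
  expect_gt(sim$summary$final_biomass, sim$config$growth$biomass_init)
})

test_that("soil mode with all soil effects zeroed equals soilless mode", {
  # om = 0 kills the multiplicative term, leaving the irrigation floor,
  # which is exactly the soilless source
  soil_cfg <- simulation_config(
    mode = "soil", soil = soil_state(7, 0, 25, si_water = 5),
    season_length = 10 * 86400, env_spec = env_spec(days = 10)
  )
  less_cfg <- short_config(si_water = 5, days = 10)
  a <- run_simulation(soil_cfg)
  b <- run_simulation(less_cfg)
  expect_identical(a$trajectory$si_total, b$trajectory$si_total)
  expect_identical(a$trajectory$biomass_total, b$trajectory$biomass_total)
})

test_that("identical configurations give identical results", {
  cfg <- reference_config()
  cfg$season_length <- 10 * 86400
  cfg$env_spec <- env_spec(days = 10)
  expect_identical(run_simulation(cfg), run_simulation(cfg))
})

test_that("stepped accumulation equals a brute-force replay of the log", {
  cfg <- simulation_config(
    mode = "soil", soil = reference_soil(25), season_length = 12 * 86400,
    env_spec = env_spec(days = 12)
  )
  sim <- run_simulation(cfg)
  tr <- sim$trajectory
  ratio <- si_convert(si_conc(1, "mg_per_L", "SiOH4"), "mg_per_L", "SiO2")$value
  vols <- diff(c(0, tr$cumulative_transpiration))
  si <- 0
  for (i in seq_along(vols)) {
    inc <- tr$si_available[i] * vols[i] * cfg$uptake$si_si / 1000 * ratio
    si <- min(si + inc, max_si_capacity(tr$biomass_total[i], cfg$uptake))
  }
  expect_rel_equal(sim$summary$final_si_total, si, 1e-9)
})

test_that("final Si is monotone in the irrigation-water concentration", {
  finals <- vapply(
    c(0, 0.5, 1, 2, 5, 20, 96.1),
    function(w) run_simulation(short_config(si_water = w, days = 10))$summary$final_si_total,
    numeric(1)
  )
  expect_true(all(diff(finals) >= 0))
})

test_that("halving the timestep moves final Si by well under 0.5%", {
  soil <- reference_soil(25)
  mk <- function(dt) run_simulation(simulation_config(
    mode = "soil", soil = soil, dt = dt,
    env_spec = env_spec(days = 119, dt = dt)
  ))$summary$final_si_total
  a <- mk(1800)
  b <- mk(900)
  expect_lt(abs(a - b) / a, 0.005)
})

test_that("an environment shorter than the season is refused", {
  cfg <- short_config(days = 10)
  env <- generate_environment(env_spec(days = 3))
  expect_error(run_simulation(cfg, env), class = "silicrop_coverage_error")
})

test_that("a season not divisible by dt is truncated and recorded", {
  cfg <- simulation_config(
    mode = "soilless", si_water = 5, season_length = 86400 + 1000,
    env_spec = env_spec(days = 2)
  )
  sim <- run_simulation(cfg)
  expect_identical(sim$summary$steps, floor((86400 + 1000) / 1800))
  expect_identical(sim$summary$effective_season, sim$summary$steps * 1800)
})

test_that("a one-point grid reproduces the scalar simulation", {
  cfg <- short_config(si_water = 5, days = 8)
  g <- run_grid(cfg, list(si_water = 5))
  sim <- run_simulation(cfg)
  expect_equal(g$final_si_total, sim$summary$final_si_total, tolerance = 1e-12)
  expect_equal(g$final_biomass, sim$summary$final_biomass, tolerance = 1e-12)
})

test_that("availability over a pH x OM grid is higher at 25 than 15 degC", {
  cfg <- simulation_config(
    mode = "soil", soil = reference_soil(), season_length = 5 * 86400,
    env_spec = env_spec(days = 5)
  )
  sweep <- list(ph = c(4, 6, 7, 8), om = c(0.5, 2, 6),
                soil_temperature = c(15, 25))
  g <- run_grid(cfg, sweep)
  g15 <- g[g$soil_temperature == 15, ]
  g25 <- g[g$soil_temperature == 25, ]
  expect_true(all(g25$areal_availability >= g15$areal_availability))
  # availability falls away as OM -> 0 and as pH -> 9
  at <- function(ph, om, t) {
    g$areal_availability[g$ph == ph & g$om == om & g$soil_temperature == t]
  }
  expect_gt(at(7, 6, 25), at(7, 2, 25))
  expect_gt(at(7, 2, 25), at(7, 0.5, 25))
  expect_gt(at(7, 6, 25), at(8, 6, 25))
})

test_that("cooler air gives less biomass but a higher Si concentration", {
  # sub-saturation irrigation Si: the 1% ceiling would mask the ordering
  cfg <- short_config(si_water = 0.5, days = 60)
  g <- run_grid(cfg, list(tair = c(20, 30)))
  expect_gt(g$final_biomass[g$tair == 30], g$final_biomass[g$tair == 20])
  expect_gt(g$final_si_conc_pct[g$tair == 20], g$final_si_conc_pct[g$tair == 30])
})

test_that("grid guards: oversize sweeps and misplaced axes are refused", {
  cfg <- short_config(days = 2)
  expect_error(run_grid(cfg, list(si_water = 1:100), max_points = 10),
               class = "silicrop_validation_error")
  expect_error(run_grid(cfg, list(ph = c(6, 7))),
               class = "silicrop_validation_error") # soil axis, soilless mode
  expect_error(run_grid(cfg, list(banana = 1)),
               class = "silicrop_validation_error")
})

test_that("a finite soil reservoir throttles late-season uptake", {
  base <- simulation_config(
    mode = "soil", soil = reference_soil(), season_length = 20 * 86400,
    env_spec = env_spec(days = 20)
  )
  finite <- simulation_config(
    mode = "soil", soil = reference_soil(), season_length = 20 * 86400,
    env_spec = env_spec(days = 20), soil_reservoir = 2000
  )
  a <- run_simulation(base)$summary$final_si_total
  b <- run_simulation(finite)$summary$final_si_total
  expect_lt(b, a)
  ratio <- si_convert(si_conc(1, "mg_per_L", "SiOH4"), "mg_per_L", "SiO2")$value
  expect_lte(b, 2000 / 1000 * ratio * (1 + 1e-9))
})
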
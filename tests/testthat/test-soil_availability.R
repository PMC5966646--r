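# Soil Si(OH)4 availability response functions and areal conversion.

test_that("temperature response matches the polynomial oracle and clamps", {
  p <- availability_params()
  temps <- c(-5, 0, 5, 8.6, 10, 15, 20, 22.9, 25, 30, 31.5, 35, 40)
  raw <- poly_oracle(temps, p$temp_coef)
  expect_equal(temperature_effect(temps, clamp = FALSE), raw, tolerance = 1e-12)
  expect_equal(temperature_effect(temps), pmin(pmax(raw, 0), 1),
               tolerance = 1e-12)
  expect_equal(temperature_effect(25), 0.6849, tolerance = 1e-9)
  expect_equal(temperature_effect(15), 0.3729, tolerance = 1e-9)
  expect_identical(temperature_effect(40), 0) # raw cubic is negative there
  expect_true(all(temperature_effect(seq(-50, 50, by = 0.1)) <= 1))
  # within the stated 8-35 degC validity range the factor stays below 1
  expect_true(all(temperature_effect(seq(8, 35, by = 0.1)) < 1))
})

test_that("organic-matter response is Michaelis-Menten and increasing", {
  expect_identical(om_effect(2.5), 0.5) # half-saturation at Km exactly
  expect_identical(om_effect(0), 0)
  expect_equal(om_effect(6), 6 / 8.5, tolerance = 1e-12)
  om <- seq(0, 50, by = 0.25)
  e <- om_effect(om)
  expect_true(all(diff(e) > 0)) # strictly increasing
  expect_true(all(e >= 0 & e < 1)) # bounded by vmax
  expect_error(om_effect(-0.1), class = "silicrop_validation_error")
})

test_that("pH response matches the oracle and clamps to [0, 1]", {
  p <- availability_params()
  phs <- c(2, 3, 5.5, 6.8, 7, 8, 8.48, 9, 9.5)
  raw <- poly_oracle(phs, p$ph_coef)
  expect_equal(ph_effect(phs, clamp = FALSE), raw, tolerance = 1e-12)
  expect_equal(ph_effect(phs), pmin(pmax(raw, 0), 1), tolerance = 1e-12)
  expect_equal(ph_effect(7), 0.9966, tolerance = 1e-9)
  expect_identical(ph_effect(9.5), 0) # raw ~ -0.58, clamped
  expect_identical(ph_effect(6.8), 1) # raw ~ 1.0022, clamped to 1
})

test_that("available_si composes the three effects over the SiP gap", {
  soil <- reference_soil(25)
  p <- availability_params()
  oracle <- (p$si_p - 5) * poly_oracle(25, p$temp_coef) * (6 / 8.5) *
    poly_oracle(7, p$ph_coef) + 5
  expect_equal(available_si(soil), oracle, tolerance = 1e-12)
  expect_equal(available_si(soil), 95.18614, tolerance = 1e-6)
  # all effects zero (om = 0) -> reduces to the irrigation floor
  expect_identical(available_si(soil_state(7, 0, 25, si_water = 5)), 5)
  # all effects forced to 1 -> the ceiling itself
  one <- availability_params(
    temp_coef = c(0, 0, 0, 1), ph_coef = c(0, 0, 0, 1)
  )
  expect_equal(
    available_si(soil_state(7, 1e12, 25, si_water = 0), one), 192.18,
    tolerance = 1e-9
  )
  expect_error(
    available_si(soil_state(7, 6, 25, si_water = 200)),
    class = "silicrop_validation_error"
  )
})

test_that("soil water volume and areal availability follow the profile", {
  expect_identical(soil_water_volume(reference_soil()), 90)
  expect_identical(
    soil_water_volume(soil_state(7, 6, 25, bulk_density = 1000)), 75
  )
  expect_equal(areal_availability(reference_soil(25)), 8566.753,
               tolerance = 1e-6)
  expect_equal(areal_availability(reference_soil(15)), 4869.240,
               tolerance = 1e-6)
  expect_gt(areal_availability(reference_soil(25)), 8300)
  expect_gt(areal_availability(reference_soil(15)), 4500)
  # soil-only term excludes the irrigation floor
  expect_equal(
    areal_availability(reference_soil(25), include_irrigation = FALSE),
    areal_availability(reference_soil(25)) - 5 * 90,
    tolerance = 1e-9
  )
})

test_that("availability grid is consistent, monotone in OM, peaks near pH 6.8", {
  soil <- reference_soil(25)
  g1 <- availability_grid(7, 6, 25, soil)
  expect_equal(unname(g1[1, 1]), areal_availability(soil), tolerance = 1e-12)
  ph <- seq(2, 9, by = 0.05)
  om <- seq(0, 6, by = 0.25)
  g <- availability_grid(ph, om, 25, soil)
  expect_true(all(apply(g, 1, function(r) all(diff(r) >= 0)))) # OM axis
  peak_ph <- ph[which(g == max(g), arr.ind = TRUE)[1, 1]]
  expect_equal(peak_ph, 6.8, tolerance = 0.1)
  expect_error(availability_grid(numeric(), om, 25, soil),
               class = "silicrop_validation_error")
})

test_that("SiAv stays in [SiWater, SiP] and matches brute force on random soils", {
  set.seed(101)
  p <- availability_params()
  n <- 1000
  for (i in seq_len(n)) {
    soil <- soil_state(
      ph = runif(1, 2, 9), om = runif(1, 0, 20),
      soil_temperature = runif(1, 0, 40), si_water = runif(1, 0, 50),
      profile_depth = runif(1, 0.1, 1), moisture = runif(1, 0.05, 0.6),
      bulk_density = runif(1, 800, 1800)
    )
    v <- available_si(soil, p)
    expect_gte(v, soil$si_water)
    expect_lte(v, p$si_p)
    brute <- (p$si_p - soil$si_water) *
      max(poly_oracle(soil$soil_temperature, p$temp_coef), 0) *
      (soil$om / (p$km + soil$om)) *
      min(max(poly_oracle(soil$ph, p$ph_coef), 0), 1) + soil$si_water
    expect_rel_equal(areal_availability(soil, p),
                     brute * soil$profile_depth * soil$bulk_density * soil$moisture,
                     1e-9)
  }
})

test_that("soil_state validates its invariants", {
  expect_error(soil_state(7, -1, 25), class = "silicrop_validation_error")
  expect_error(soil_state(7, 6, 25, moisture = 0), class = "silicrop_validation_error")
  expect_error(soil_state(7, 6, 25, moisture = 1), class = "silicrop_validation_error")
  expect_error(soil_state(7, 6, 25, profile_depth = 0), class = "silicrop_validation_error")
  expect_error(soil_state(7, 6, 25, si_water = -2), class = "silicrop_validation_error")
  expect_error(soil_state(7, 6, NA), class = "silicrop_validation_error")
})
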
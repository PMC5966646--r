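# Shared scenario builders. The reference soil scenario: pH 7, 6% organic
# matter, 5 mg/L Si(OH)4 in irrigation water, 30 cm profile at 25% w/w
# moisture and 1200 kg/m3 bulk density; aerial inputs PAR 400 for 12 h/day,
# CO2 400 uL/L, air 30 degC.

reference_soil <- function(soil_temperature = 25) {
  soil_state(
    ph = 7, om = 6, soil_temperature = soil_temperature, si_water = 5,
    profile_depth = 0.30, moisture = 0.25, bulk_density = 1200
  )
}

# full crop season (tcg seconds, ~119 days) in the reference environment
reference_config <- function(soil_temperature = 25, tair = 30, ...) {
  simulation_config(
    mode = "soil", soil = reference_soil(soil_temperature),
    env_spec = env_spec(days = 119, tair_day = tair),
    ...
  )
}

# short season for property tests where absolute magnitudes don't matter
short_config <- function(mode = "soilless", si_water = 5, days = 14,
                         tair = 30, dt = 1800, ...) {
  simulation_config(
    mode = mode, si_water = if (mode == "soilless") si_water,
    season_length = days * 86400, dt = dt,
    env_spec = env_spec(days = days, tair_day = tair, dt = dt),
    ...
  )
}

# independent polynomial oracle: plain power-sum evaluation, no Horner
poly_oracle <- function(x, coef_desc) {
  vapply(x, function(xi) sum(coef_desc * xi^(3:0)), numeric(1))
}

expect_rel_equal <- function(object, expected, tol) {
  expect_lt(abs(object - expected), tol * max(abs(expected), 1e-300))
}
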
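# Reduced crop growth driver and transpiration.
#
# The literature six-state greenhouse tomato model this simulator stands in
# for is not reproducible from published coefficients, so biomass dynamics
# are provided by a pluggable GrowthDriver: a function
# (biomass_total, env_sample, dt, params) -> biomass increment (g dry/m2).
# The default driver is light-limited potential growth
#   dB/dt = rue * PAR * f_CO2(CO2) * f_T(Tair) * (1 - B/Bmax)
# with a Michaelis-Menten CO2 factor, a beta-type cardinal temperature
# suitability, and a saturating ceiling. `rue` is calibrated so a season at
# PAR 400 (12 h/day), CO2 400 and 30 degC air ends at 1370 g dry biomass
# per plant (4110 g/m2 at 3 plants/m2), the anchor implied by a 1% Si cap
# of 13.7 g SiO2 per plant.
#
# Transpiration is the linear relation Transpiration = Biomass * plm / tcg,
# read as L of water per m2 of ground per second.

#' Growth and transpiration parameters
#'
#' @param plm Slope of the biomass-transpiration linear relation (8.5714).
#' @param tcg Crop season length, seconds (10279801 s, ~119 days).
#' @param pd Planting density, plants/m2.
#' @param rue Effective radiation-use coefficient, g dry biomass per umol
#'   photons (calibrated anchor value; see package vignette).
#' @param co2_half_sat CO2 half-saturation of the assimilation response,
#'   uL/L.
#' @param t_min,t_opt,t_max Cardinal air temperatures of the growth
#'   response, degC.
#' @param biomass_max Biomass asymptote, g dry/m2 (3000 g/plant at
#'   `pd = 3`).
#' @param biomass_init Transplant biomass, g dry/m2.
#' @param partition_20,partition_30 Organ dry-mass fractions (leaf, stem,
#'   fruit, root) at the 20 and 30 degC anchor regimes; linearly
#'   interpolated in between, constant outside.
#' @param leaf_weighting Scale whole-plant transpiration by the leaf dry
#'   mass share relative to the 30 degC reference canopy (leaves dominate
#'   transpiration, so leafier low-temperature canopies transpire more per
#'   unit biomass). `TRUE` by default; at 30 degC the weight is exactly 1,
#'   so the calibration anchor is unaffected.
#' @param driver A GrowthDriver function; defaults to
#'   [default_growth_driver].
#' @return A list of class `growth_params`.
#' @export
growth_params <- function(plm = 8.5714, tcg = 10279801, pd = 3,
                          rue = 4.66682277422e-06, co2_half_sat = 300,
                          t_min = 8, t_opt = 30, t_max = 40,
                          biomass_max = 9000, biomass_init = 6,
                          partition_20 = c(leaf = 0.33, stem = 0.27,
                                           fruit = 0.33, root = 0.07),
                          partition_30 = c(leaf = 0.09, stem = 0.25,
                                           fruit = 0.60, root = 0.06),
                          leaf_weighting = TRUE,
                          driver = default_growth_driver) {
  stopifnot(
    plm > 0, tcg > 0, pd > 0, rue > 0, co2_half_sat > 0,
    t_min < t_opt, t_opt < t_max,
    biomass_max > biomass_init, biomass_init > 0,
    is.function(driver), is.logical(leaf_weighting)
  )
  for (p in list(partition_20, partition_30)) {
    if (!identical(names(p), c("leaf", "stem", "fruit", "root")) ||
        any(p < 0) || abs(sum(p) - 1) > 1e-9) {
      si_abort("organ partition fractions must be named leaf/stem/fruit/root, >= 0, and sum to 1")
    }
  }
  structure(
    list(
      plm = plm, tcg = tcg, pd = pd, rue = rue,
      co2_half_sat = co2_half_sat,
      t_min = t_min, t_opt = t_opt, t_max = t_max,
      biomass_max = biomass_max, biomass_init = biomass_init,
      partition_20 = partition_20, partition_30 = partition_30,
      leaf_weighting = leaf_weighting, driver = driver
    ),
    class = "growth_params"
  )
}

#' Create a plant state
#'
#' @param biomass_total Total dry biomass, g/m2.
#' @param organ_biomass Named vector (leaf, stem, fruit, root), g/m2,
#'   summing to `biomass_total`.
#' @param cumulative_transpiration Water transpired since transplant, L/m2.
#' @return A list of class `plant_state`.
#' @export
plant_state <- function(biomass_total,
                        organ_biomass = biomass_total *
                          c(leaf = 0.25, stem = 0.25, fruit = 0.25, root = 0.25),
                        cumulative_transpiration = 0) {
  stopifnot(biomass_total >= 0, cumulative_transpiration >= 0)
  if (any(organ_biomass < 0) ||
      abs(sum(organ_biomass) - biomass_total) >
        1e-9 * max(1, biomass_total)) {
    si_abort("organ biomasses must be >= 0 and sum to biomass_total")
  }
  structure(
    list(
      biomass_total = biomass_total,
      organ_biomass = organ_biomass[c("leaf", "stem", "fruit", "root")],
      cumulative_transpiration = cumulative_transpiration
    ),
    class = "plant_state"
  )
}

# CO2 saturation factor, in (0, 1), increasing
.co2_factor <- function(co2, params) co2 / (co2 + params$co2_half_sat)

# Beta-type cardinal temperature suitability in [0, 1], 1 at t_opt,
# 0 at/outside the cardinal limits.
.temp_suitability <- function(tair, params) {
  with(params, {
    q <- (t_max - t_opt) / (t_opt - t_min)
    f <- ((tair - t_min) / (t_opt - t_min)) *
      ((t_max - tair) / (t_max - t_opt))^q
    f[tair <= t_min | tair >= t_max] <- 0
    pmin(pmax(f, 0), 1)
  })
}

#' Default reduced growth driver
#'
#' Light-limited potential growth with CO2 and temperature modifiers and a
#' saturating biomass ceiling (see file header). Returns the biomass
#' increment over `dt`; zero in the dark.
#'
#' @param biomass_total Current dry biomass, g/m2.
#' @param env A one-row environment sample with fields `par`, `tair_c`,
#'   `co2_ppm`.
#' @param dt Timestep, s.
#' @param params A [growth_params()] object.
#' @return Biomass increment, g/m2 (>= 0).
#' @export
default_growth_driver <- function(biomass_total, env, dt, params) {
  if (env$par <= 0) return(0)
  ceiling_frac <- max(0, 1 - biomass_total / params$biomass_max)
  rate <- params$rue * env$par * .co2_factor(env$co2_ppm, params) *
    .temp_suitability(env$tair_c, params)
  # never overshoot the asymptote even at extreme forcing
  min(rate * dt * ceiling_frac, params$biomass_max - biomass_total)
}

#' Constant-biomass stub driver
#'
#' A GrowthDriver that never grows: useful to test that silicon uptake
#' depends only on the driver contract, not on driver internals.
#'
#' @inheritParams default_growth_driver
#' @return Always 0.
#' @export
constant_growth_driver <- function(biomass_total, env, dt, params) 0

#' Organ dry-mass partition fractions
#'
#' Linear interpolation between the 20 degC regime (fruit ~33%, leaf ~33%)
#' and the 30 degC regime (fruit ~60%, leaf < 10%), held constant outside
#' the 20-30 degC band.
#'
#' @param tair Air temperature, degC.
#' @param params A [growth_params()] object.
#' @return Named fractions (leaf, stem, fruit, root) summing to 1.
#' @examples
#' partition_fractions(30) # fruit 0.60, leaf 0.09
#' @export
partition_fractions <- function(tair, params = growth_params()) {
  stopifnot(is.numeric(tair), length(tair) == 1L, is.finite(tair))
  w <- min(max((tair - 20) / 10, 0), 1)
  f <- (1 - w) * params$partition_20 + w * params$partition_30
  f / sum(f)
}

#' Whole-plant transpiration rate
#'
#' The linear relation `Biomass * plm / tcg`, with biomass in g dry/m2 and
#' the result read as L of water per m2 of ground per second.
#'
#' @param biomass_total Dry biomass, g/m2 (vectorized).
#' @param params A [growth_params()] object.
#' @return Transpiration rate, L/m2/s.
#' @examples
#' transpiration_rate(1000) # 8.3381e-4 L/m2/s
#' @export
transpiration_rate <- function(biomass_total, params = growth_params()) {
  stopifnot(is.numeric(biomass_total), all(biomass_total >= 0))
  biomass_total * params$plm / params$tcg
}

# transpiration multiplier for leaf-share weighting (1 when disabled or at
# the 30 degC reference partition)
.leaf_weight <- function(tair, params) {
  if (!params$leaf_weighting) return(1)
  partition_fractions(tair, params)[["leaf"]] / params$partition_30[["leaf"]]
}

#' Advance the plant state by one timestep
#'
#' Applies the growth driver, re-partitions organ dry mass from the current
#' air temperature, and accumulates transpired water (transpiration runs
#' day and night; growth only under light).
#'
#' @param state A [plant_state()].
#' @inheritParams default_growth_driver
#' @return The updated `plant_state`.
#' @export
growth_step <- function(state, env, dt, params = growth_params()) {
  stopifnot(inherits(state, "plant_state"), dt > 0)
  inc <- params$driver(state$biomass_total, env, dt, params)
  if (inc < 0) si_abort("growth driver returned a negative increment")
  total <- state$biomass_total + inc
  organ <- total * partition_fractions(env$tair_c, params)
  transp <- transpiration_rate(total, params) * .leaf_weight(env$tair_c, params) * dt
  plant_state(
    biomass_total = total,
    organ_biomass = organ,
    cumulative_transpiration = state$cumulative_transpiration + transp
  )
}
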
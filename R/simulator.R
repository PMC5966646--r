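# Season-scale time stepping: growth -> transpiration -> Si uptake.
#
# Explicit-Euler stepping on a uniform grid. Soil cultivation re-evaluates
# the soil-solution availability from the (static) soil state each step --
# the soil Si pool is treated as non-depleting, matching the assumption of
# unlimited replenishment from the mineral phase; an optional finite
# reservoir can be enabled for sensitivity studies. Soilless cultivation
# draws on the irrigation-water concentration directly.

#' Configure a simulation
#'
#' @param mode `"soil"` or `"soilless"`.
#' @param soil A [soil_state()]; required in soil mode.
#' @param si_water Irrigation-water Si(OH)4, mg/L; required in soilless
#'   mode (soil mode reads it from `soil`).
#' @param season_length Season duration, s. Defaults to the crop-season
#'   parameter `tcg` of `growth`.
#' @param dt Timestep, s. Should divide `season_length`; a remainder
#'   shorter than one step is truncated and recorded in the result
#'   metadata (the default season of 10279801 s is not a multiple of any
#'   round timestep).
#' @param growth A [growth_params()].
#' @param uptake An [uptake_params()].
#' @param availability An [availability_params()].
#' @param env_spec An [env_spec()] used to synthesize the environment when
#'   [run_simulation()] is not handed one explicitly; `NULL` by default
#'   (an `env_spec` covering the season is then derived from defaults).
#' @param mulch_offset Soil-temperature increase from plastic mulching,
#'   degC (typically 0-4).
#' @param soil_reservoir Finite areal soil Si reservoir, mg/m2 Si(OH)4, or
#'   `Inf` (default) for the non-depleting assumption.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(mode = c("soil", "soilless"), soil = NULL,
                              si_water = NULL, season_length = NULL,
                              dt = 1800, growth = growth_params(),
                              uptake = uptake_params(),
                              availability = availability_params(),
                              env_spec = NULL, mulch_offset = 0,
                              soil_reservoir = Inf) {
  mode <- match.arg(mode)
  stopifnot(
    inherits(growth, "growth_params"), inherits(uptake, "uptake_params"),
    inherits(availability, "availability_params"),
    is.numeric(dt), dt > 0, is.numeric(mulch_offset),
    is.numeric(soil_reservoir), soil_reservoir > 0
  )
  if (is.null(season_length)) season_length <- growth$tcg
  if (season_length < dt) si_abort("season_length must cover at least one timestep")
  if (mode == "soil") {
    if (!inherits(soil, "soil_state")) {
      si_abort("soil mode requires a soil_state in 'soil'")
    }
    si_water <- soil$si_water
  } else {
    if (is.null(si_water)) {
      si_abort("soilless mode requires 'si_water' (mg/L Si(OH)4)")
    }
    if (!is.numeric(si_water) || si_water < 0) {
      si_abort("si_water must be >= 0")
    }
  }
  if (!is.null(env_spec) && !inherits(env_spec, "env_spec")) {
    si_abort("env_spec must be built with env_spec()")
  }
  structure(
    list(
      mode = mode, soil = soil, si_water = as.numeric(si_water),
      season_length = as.numeric(season_length), dt = as.numeric(dt),
      growth = growth, uptake = uptake, availability = availability,
      env_spec = env_spec, mulch_offset = as.numeric(mulch_offset),
      soil_reservoir = as.numeric(soil_reservoir)
    ),
    class = "simulation_config"
  )
}

# environment to use for a config: explicit > config$env_spec > defaults
.config_environment <- function(config, environment = NULL) {
  if (!is.null(environment)) {
    return(as_si_environment(environment))
  }
  spec <- config$env_spec
  if (is.null(spec)) {
    spec <- env_spec(
      days = ceiling(config$season_length / 86400), dt = config$dt
    )
  }
  generate_environment(spec)
}

#' Run a full-season simulation
#'
#' Per step: advance growth and transpiration, pick the Si(OH)4 source
#' concentration (soil-solution availability in soil mode, irrigation
#' water in soilless mode), and accumulate silicon against the running
#' 1%-of-biomass cap.
#'
#' @param config A [simulation_config()].
#' @param environment An `si_environment` covering the season; synthesized
#'   from `config$env_spec` (or defaults) when `NULL`.
#' @return A list of class `si_simulation` with elements `trajectory`
#'   (one row per step: biomass, organ biomass, transpiration, available
#'   Si, Si account, concentration), `summary` (final/maximum figures, per
#'   area and per plant) and `config`.
#' @examples
#' cfg <- simulation_config(
#'   mode = "soilless", si_water = 5,
#'   season_length = 10 * 86400,
#'   env_spec = env_spec(days = 10)
#' )
#' sim <- run_simulation(cfg)
#' sim$summary$final_biomass_per_plant
#' @export
run_simulation <- function(config, environment = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  env <- .config_environment(config, environment)
  dt <- if (is.null(environment)) config$dt else attr(env, "dt")
  n <- floor(config$season_length / dt)
  if (nrow(env) < n) {
    si_abort(sprintf(
      "environment (%d steps) does not cover the season (%d steps of %g s)",
      nrow(env), n, dt
    ), class = "silicrop_coverage_error")
  }

  gp <- config$growth
  up <- config$uptake
  if (config$mode == "soil") {
    soil <- config$soil
    soil$soil_temperature <- soil$soil_temperature + config$mulch_offset
    conc_source <- available_si(soil, config$availability)
  } else {
    conc_source <- config$si_water
  }

  state <- plant_state(
    gp$biomass_init,
    gp$biomass_init * partition_fractions(env$tair_c[1L], gp)
  )
  account <- si_account()
  reservoir <- config$soil_reservoir

  organs <- c("leaf", "stem", "fruit", "root")
  traj <- data.frame(
    time_s = env$time_s[seq_len(n)] + dt,
    biomass_total = numeric(n),
    transpiration_rate = numeric(n), cumulative_transpiration = numeric(n),
    si_available = numeric(n), si_total = numeric(n),
    si_conc_pct = numeric(n)
  )
  organ_bm <- matrix(0, n, 4L, dimnames = list(NULL, paste0("biomass_", organs)))
  organ_si <- matrix(0, n, 4L, dimnames = list(NULL, paste0("si_", organs)))

  for (i in seq_len(n)) {
    e <- env[i, ]
    prev_transp <- state$cumulative_transpiration
    state <- growth_step(state, e, dt, gp)
    vol <- state$cumulative_transpiration - prev_transp

    conc <- conc_source
    if (is.finite(reservoir)) {
      # finite reservoir: uptake cannot draw more Si(OH)4 than remains
      drawable <- min(conc * vol, reservoir)
      conc <- if (vol > 0) drawable / vol else 0
    }
    pre_total <- account$total_si
    cap <- max_si_capacity(state$biomass_total, up)
    account <- uptake_step(account, conc, vol, cap, up)
    if (is.finite(reservoir)) {
      reservoir <- reservoir -
        (account$total_si - pre_total) / .sioh4_to_sio2() * 1000
    }

    traj$biomass_total[i] <- state$biomass_total
    organ_bm[i, ] <- state$organ_biomass
    traj$transpiration_rate[i] <- transpiration_rate(state$biomass_total, gp)
    traj$cumulative_transpiration[i] <- state$cumulative_transpiration
    traj$si_available[i] <- conc_source
    traj$si_total[i] <- account$total_si
    organ_si[i, ] <- account$organ_si
    traj$si_conc_pct[i] <- si_concentration_pct(account, state$biomass_total)
  }

  traj <- cbind(traj, as.data.frame(organ_bm), as.data.frame(organ_si))
  pd <- gp$pd
  summary <- list(
    mode = config$mode,
    steps = n, dt = dt, effective_season = n * dt,
    si_source_mg_per_L = conc_source,
    final_biomass = state$biomass_total,
    final_biomass_per_plant = state$biomass_total / pd,
    final_si_total = account$total_si,
    final_si_per_plant = account$total_si / pd,
    final_si_conc_pct = traj$si_conc_pct[n],
    max_si_conc_pct = max(traj$si_conc_pct),
    cumulative_transpiration = state$cumulative_transpiration,
    organ_si = account$organ_si,
    organ_biomass = state$organ_biomass
  )
  structure(
    list(trajectory = traj, summary = summary, config = config),
    class = "si_simulation"
  )
}

#' @export
print.si_simulation <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<si_simulation> %s mode, %d steps of %g s\n", s$mode, s$steps, s$dt
  ))
  cat(sprintf(
    "  biomass %.1f g/m2 (%.1f g/plant); Si %.2f g SiO2/m2 (%.2f g/plant, %.2f%% dw)\n",
    s$final_biomass, s$final_biomass_per_plant,
    s$final_si_total, s$final_si_per_plant, s$final_si_conc_pct
  ))
  invisible(x)
}

#' Run a scenario sweep
#'
#' Evaluates [run_simulation()] over the cartesian product of the supplied
#' axes. Edaphic axes (`ph`, `om`, `soil_temperature`, `si_water`) modify
#' the soil/irrigation inputs; aerial axes (`par`, `co2`, `tair`) modify
#' the synthetic environment spec. Rows are ordered as `expand.grid` of
#' the axes (first axis varying fastest), deterministically.
#'
#' @param config A [simulation_config()] giving the baseline scenario.
#' @param sweep Named list of axis vectors; allowed names: `ph`, `om`,
#'   `soil_temperature`, `si_water`, `par`, `co2`, `tair`.
#' @param max_points Refuse cartesian products larger than this.
#' @return A data frame with one row per grid point: the axis coordinates
#'   plus final biomass, Si accumulation (per m2 and per plant), Si
#'   concentration (% dw) and, in soil mode, the areal availability.
#' @export
run_grid <- function(config, sweep, max_points = 5000) {
  stopifnot(inherits(config, "simulation_config"), is.list(sweep))
  allowed <- c("ph", "om", "soil_temperature", "si_water", "par", "co2", "tair")
  bad <- setdiff(names(sweep), allowed)
  if (length(bad) > 0 || is.null(names(sweep)) || any(names(sweep) == "")) {
    si_abort(sprintf(
      "unknown sweep axes: %s (allowed: %s)", toString(bad), toString(allowed)
    ))
  }
  if (any(lengths(sweep) == 0)) si_abort("sweep axes must be non-empty")
  pts <- expand.grid(sweep, KEEP.OUT.ATTRS = FALSE)
  if (nrow(pts) > max_points) {
    si_abort(sprintf(
      "sweep has %d points, above the limit of %d", nrow(pts), max_points
    ))
  }
  soil_axes <- intersect(names(sweep), c("ph", "om", "soil_temperature"))
  if (length(soil_axes) > 0 && config$mode != "soil") {
    si_abort("axes over soil properties require soil mode")
  }

  rows <- vector("list", nrow(pts))
  for (i in seq_len(nrow(pts))) {
    cfg <- config
    p <- pts[i, , drop = FALSE]
    if (cfg$mode == "soil") {
      s <- cfg$soil
      if (!is.null(p$ph)) s$ph <- p$ph
      if (!is.null(p$om)) s$om <- p$om
      if (!is.null(p$soil_temperature)) s$soil_temperature <- p$soil_temperature
      if (!is.null(p$si_water)) s$si_water <- p$si_water
      cfg$soil <- do.call(soil_state, unclass(s))
      cfg$si_water <- cfg$soil$si_water
    } else if (!is.null(p$si_water)) {
      cfg$si_water <- p$si_water
    }
    es <- cfg$env_spec
    if (is.null(es)) {
      es <- env_spec(days = ceiling(cfg$season_length / 86400), dt = cfg$dt)
    }
    if (!is.null(p$par)) es$par_day <- p$par
    if (!is.null(p$co2)) es$co2 <- p$co2
    if (!is.null(p$tair)) {
      es$tair_day <- p$tair
      es$tair_night <- p$tair
    }
    cfg$env_spec <- es
    sim <- run_simulation(cfg)
    s <- sim$summary
    rows[[i]] <- cbind(p, data.frame(
      final_biomass = s$final_biomass,
      final_biomass_per_plant = s$final_biomass_per_plant,
      final_si_total = s$final_si_total,
      final_si_per_plant = s$final_si_per_plant,
      final_si_conc_pct = s$final_si_conc_pct,
      areal_availability = if (cfg$mode == "soil") {
        soil2 <- cfg$soil
        soil2$soil_temperature <- soil2$soil_temperature + cfg$mulch_offset
        areal_availability(do.call(soil_state, unclass(soil2)), cfg$availability)
      } else {
        NA_real_
      }
    ))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
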
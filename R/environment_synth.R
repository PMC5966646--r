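# Synthetic greenhouse environment series.
#
# The simulation scenarios in this package use a square-wave light regime:
# constant PAR for a fixed photoperiod, dark otherwise, with day/night air
# temperature levels and constant CO2. Optional Gaussian perturbation
# (seeded, own RNG stream) roughens the series without touching global
# RNG state. A sinusoidal light option exists for users who want a softer
# diurnal course.

#' Specify a synthetic environment
#'
#' @param days Number of whole days to generate.
#' @param photoperiod_h Daily light hours, in (0, 24].
#' @param par_day PAR during the photoperiod, umol/m2/s.
#' @param co2 CO2 concentration, uL/L.
#' @param tair_day,tair_night Air temperature in/outside the photoperiod,
#'   degC. The reference scenarios use a single average temperature, so
#'   `tair_night` defaults to `tair_day`.
#' @param dt Sampling step, s; must divide 86400.
#' @param seed Integer seed for the optional noise.
#' @param noise_sd Named list of Gaussian standard deviations
#'   (`par`, `tair`, `co2`); all zero by default (deterministic series).
#' @param par_shape `"square"` (default) or `"sine"` (half-sine arch over
#'   the photoperiod with the same daily light integral).
#' @return A list of class `env_spec`.
#' @export
env_spec <- function(days, photoperiod_h = 12, par_day = 400, co2 = 400,
                     tair_day = 30, tair_night = tair_day, dt = 1800,
                     seed = 1L,
                     noise_sd = list(par = 0, tair = 0, co2 = 0),
                     par_shape = c("square", "sine")) {
  par_shape <- match.arg(par_shape)
  if (!is.numeric(days) || days < 1 || days != round(days)) {
    si_abort("days must be a whole number >= 1")
  }
  if (photoperiod_h <= 0 || photoperiod_h > 24) {
    si_abort("photoperiod_h must lie in (0, 24]")
  }
  stopifnot(par_day >= 0, co2 > 0, dt > 0)
  if (86400 %% dt != 0) si_abort("dt must divide the 86400 s day")
  sd_full <- list(par = 0, tair = 0, co2 = 0)
  sd_full[names(noise_sd)] <- noise_sd
  if (any(unlist(sd_full) < 0)) si_abort("noise_sd values must be >= 0")
  structure(
    list(
      days = as.integer(days), photoperiod_h = photoperiod_h,
      par_day = par_day, co2 = co2,
      tair_day = tair_day, tair_night = tair_night,
      dt = dt, seed = as.integer(seed), noise_sd = sd_full,
      par_shape = par_shape
    ),
    class = "env_spec"
  )
}

#' Validate and tag an environment series
#'
#' @param df A data frame with columns `time_s`, `par`, `tair_c`,
#'   `co2_ppm`, uniformly sampled in `time_s`.
#' @return The data frame with class `si_environment` and a `dt` attribute.
#' @export
as_si_environment <- function(df) {
  need <- c("time_s", "par", "tair_c", "co2_ppm")
  if (!all(need %in% names(df))) {
    si_abort(sprintf("environment needs columns: %s", toString(need)))
  }
  df <- as.data.frame(df)[need]
  if (nrow(df) < 1L || any(!is.finite(as.matrix(df)))) {
    si_abort("environment values must be finite and non-empty")
  }
  steps <- diff(df$time_s)
  if (nrow(df) > 1L &&
      (any(steps <= 0) || diff(range(steps)) > 1e-6 * steps[1L])) {
    si_abort("environment time must be strictly increasing with a uniform step")
  }
  if (any(df$par < 0)) si_abort("PAR must be >= 0")
  if (any(df$co2_ppm <= 0)) si_abort("CO2 must be > 0")
  dt <- if (nrow(df) > 1L) steps[1L] else NA_real_
  structure(df, class = c("si_environment", "data.frame"), dt = dt)
}

#' Generate a synthetic environment series
#'
#' @param spec An [env_spec()].
#' @return An `si_environment` data frame of `days * 86400 / dt` rows with
#'   columns `time_s`, `par`, `tair_c`, `co2_ppm`.
#' @examples
#' env <- generate_environment(env_spec(days = 2))
#' mean(env$par > 0) # half the samples are lit at a 12 h photoperiod
#' @export
generate_environment <- function(spec) {
  stopifnot(inherits(spec, "env_spec"))
  n <- spec$days * 86400L %/% spec$dt
  time_s <- (seq_len(n) - 1) * spec$dt
  tod <- time_s %% 86400
  phot <- spec$photoperiod_h * 3600
  lit <- tod < phot
  par <- if (spec$par_shape == "square") {
    ifelse(lit, spec$par_day, 0)
  } else {
    # half-sine arch, rescaled to the same daily light integral
    ifelse(lit, spec$par_day * (pi / 2) * sin(pi * tod / phot), 0)
  }
  tair <- ifelse(lit, spec$tair_day, spec$tair_night)
  co2 <- rep(spec$co2, n)
  if (any(unlist(spec$noise_sd) > 0)) {
    rng <- .seeded_rng(spec$seed)
    if (spec$noise_sd$par > 0) {
      par <- pmax(par + ifelse(lit, rng(n, spec$noise_sd$par), 0), 0)
    }
    if (spec$noise_sd$tair > 0) tair <- tair + rng(n, spec$noise_sd$tair)
    if (spec$noise_sd$co2 > 0) {
      co2 <- pmax(co2 + rng(n, spec$noise_sd$co2), 1e-6)
    }
  }
  as_si_environment(data.frame(
    time_s = time_s, par = par, tair_c = tair, co2_ppm = co2
  ))
}

# Gaussian draws from a private RNG stream; global .Random.seed untouched.
.seeded_rng <- function(seed) {
  state <- local({
    orig <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    on.exit(
      if (is.null(orig)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", orig, envir = globalenv())
      }
    )
    set.seed(seed)
    get(".Random.seed", globalenv())
  })
  function(n, sd) {
    orig <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    assign(".Random.seed", state, envir = globalenv())
    out <- stats::rnorm(n, 0, sd)
    state <<- get(".Random.seed", globalenv())
    if (is.null(orig)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", orig, envir = globalenv())
    }
    out
  }
}
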
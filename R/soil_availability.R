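# Bioavailable Si(OH)4 in the soil solution.
#
# Availability of orthosilicic acid is modelled as the product of three
# unitless response factors -- a cubic in soil temperature, a
# Michaelis-Menten saturation in organic matter, and a cubic in pH --
# scaling the gap between the irrigation-water contribution and the
# polymerization ceiling (192.18 mg/L Si(OH)4, i.e. 2 mM).

#' Parameters of the soil Si availability response functions
#'
#' Defaults are the published coefficients: a cubic temperature response
#' (valid roughly between 8 and 35 degC), a Michaelis-Menten organic-matter
#' response with half-saturation `km = 2.5`% w/w, a cubic pH response
#' (meaningful over pH 2-9), and the polymerization ceiling
#' `si_p = 192.18` mg/L Si(OH)4 above which silica polymerizes and becomes
#' unavailable.
#'
#' @param temp_coef Cubic temperature coefficients, highest degree first.
#' @param ph_coef Cubic pH coefficients, highest degree first.
#' @param vmax Maximum of the organic-matter response (normalized to 1).
#' @param km Half-saturation organic-matter content, % w/w.
#' @param si_p Polymerization ceiling, mg/L Si(OH)4.
#' @return A list of class `availability_params`.
#' @export
availability_params <- function(temp_coef = c(-0.0003, 0.0127, -0.1093, 0.1674),
                                ph_coef = c(-0.0235, 0.325, -1.1563, 1.2262),
                                vmax = 1, km = 2.5, si_p = 192.18) {
  stopifnot(
    length(temp_coef) == 4L, length(ph_coef) == 4L,
    is.numeric(vmax), vmax > 0, is.numeric(km), km > 0,
    is.numeric(si_p), si_p > 0
  )
  structure(
    list(
      temp_coef = as.numeric(temp_coef), ph_coef = as.numeric(ph_coef),
      vmax = vmax, km = km, si_p = si_p
    ),
    class = "availability_params"
  )
}

#' Describe the edaphic state of a cultivated soil
#'
#' @param ph Soil pH (meaningful range 2-9).
#' @param om Organic-matter content, % w/w (>= 0).
#' @param soil_temperature Mean 0-30 cm soil temperature, degC.
#' @param si_water Si(OH)4 concentration of the irrigation water, mg/L.
#' @param profile_depth Rooted soil profile depth, m.
#' @param moisture Gravimetric soil moisture, fraction w/w in (0, 1).
#' @param bulk_density Dry bulk density, kg/m3.
#' @return A list of class `soil_state`.
#' @examples
#' soil_state(ph = 7, om = 6, soil_temperature = 25, si_water = 5)
#' @export
soil_state <- function(ph, om, soil_temperature, si_water = 0,
                       profile_depth = 0.30, moisture = 0.25,
                       bulk_density = 1200) {
  for (nm in c("ph", "om", "soil_temperature", "si_water", "profile_depth",
               "moisture", "bulk_density")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      si_abort(sprintf("soil_state field '%s' must be a finite numeric scalar", nm))
    }
  }
  if (om < 0) si_abort("organic matter (om) must be >= 0")
  if (si_water < 0) si_abort("si_water must be >= 0")
  if (profile_depth <= 0) si_abort("profile_depth must be > 0")
  if (moisture <= 0 || moisture >= 1) si_abort("moisture must lie in (0, 1)")
  if (bulk_density <= 0) si_abort("bulk_density must be > 0")
  structure(
    list(
      ph = ph, om = om, soil_temperature = soil_temperature,
      si_water = si_water, profile_depth = profile_depth,
      moisture = moisture, bulk_density = bulk_density
    ),
    class = "soil_state"
  )
}

#' @export
print.soil_state <- function(x, ...) {
  cat(sprintf(
    "<soil_state> pH %.2f | OM %.1f%% | %.1f degC | SiWater %.2f mg/L Si(OH)4\n",
    x$ph, x$om, x$soil_temperature, x$si_water
  ))
  cat(sprintf(
    "  profile %.2f m, moisture %.2f w/w, bulk density %.0f kg/m3\n",
    x$profile_depth, x$moisture, x$bulk_density
  ))
  invisible(x)
}

.cubic <- function(x, coef) {
  ((coef[1L] * x + coef[2L]) * x + coef[3L]) * x + coef[4L]
}

#' Temperature response of soil Si availability
#'
#' Cubic response, clamped to `[0, 1]`: the raw polynomial is negative
#' between ~2 and ~8.6 degC and above ~31.5 degC, where availability is
#' treated as nil, and diverges above 1 at deeply sub-zero temperatures
#' outside the polynomial's validity range (roughly 8-35 degC). The raw
#' cubic peaks near 23 degC at ~0.72. The upper clamp preserves the bound
#' that availability can never exceed the polymerization ceiling.
#'
#' @param temp Soil temperature, degC (vectorized).
#' @param params An [availability_params()] object.
#' @param clamp Clamp to `[0, 1]` (default). `clamp = FALSE` returns the
#'   raw polynomial, useful for diagnostics.
#' @return Unitless factor(s) in `[0, 1]` when clamped.
#' @examples
#' temperature_effect(25) # 0.6849
#' @export
temperature_effect <- function(temp, params = availability_params(), clamp = TRUE) {
  stopifnot(is.numeric(temp), all(is.finite(temp)))
  raw <- .cubic(temp, params$temp_coef)
  if (clamp) pmin(pmax(raw, 0), 1) else raw
}

#' Organic-matter response of soil Si availability
#'
#' Michaelis-Menten saturation `vmax * om / (km + om)`: strictly increasing,
#' half-saturated at `om = km` (2.5% w/w by default), approaching `vmax`.
#'
#' @param om Organic matter, % w/w (vectorized, >= 0).
#' @inheritParams temperature_effect
#' @return Unitless factor(s) in `[0, vmax)`.
#' @examples
#' om_effect(2.5) # exactly 0.5
#' @export
om_effect <- function(om, params = availability_params()) {
  stopifnot(is.numeric(om), all(is.finite(om)))
  if (any(om < 0)) si_abort("organic matter must be >= 0")
  params$vmax * om / (params$km + om)
}

#' pH response of soil Si availability
#'
#' Cubic response clamped to `[0, 1]`: the raw polynomial slightly exceeds 1
#' near its maximum (pH ~6.8) and turns negative above pH ~9.1.
#'
#' @param ph Soil pH (vectorized).
#' @inheritParams temperature_effect
#' @return Unitless factor(s) in `[0, 1]` when clamped.
#' @examples
#' ph_effect(7) # 0.9966
#' @export
ph_effect <- function(ph, params = availability_params(), clamp = TRUE) {
  stopifnot(is.numeric(ph), all(is.finite(ph)))
  raw <- .cubic(ph, params$ph_coef)
  if (clamp) pmin(pmax(raw, 0), 1) else raw
}

#' Bioavailable Si(OH)4 concentration in the soil solution
#'
#' Composes the three response factors over the gap between the
#' polymerization ceiling and the irrigation-water contribution:
#' `(si_p - si_water) * E_temp * E_om * E_ph + si_water`. The result is
#' bounded in `[si_water, si_p]` by construction; an explicit cap at `si_p`
#' guards user-supplied parameter overrides.
#'
#' @param soil A [soil_state()].
#' @param params An [availability_params()].
#' @param include_irrigation If `FALSE`, return only the soil-derived term
#'   (the product term without the additive `si_water` floor).
#' @return mg/L Si(OH)4 in the soil solution.
#' @examples
#' available_si(soil_state(7, 6, 25, si_water = 5)) # ~95.2 mg/L
#' @export
available_si <- function(soil, params = availability_params(),
                         include_irrigation = TRUE) {
  stopifnot(inherits(soil, "soil_state"))
  if (soil$si_water > params$si_p) {
    si_abort("irrigation-water Si(OH)4 exceeds the polymerization ceiling si_p")
  }
  e <- temperature_effect(soil$soil_temperature, params) *
    om_effect(soil$om, params) *
    ph_effect(soil$ph, params)
  soil_term <- (params$si_p - soil$si_water) * e
  out <- if (include_irrigation) soil_term + soil$si_water else soil_term
  min(out, params$si_p)
}

#' Soil water volume per unit ground area
#'
#' `profile_depth * bulk_density * moisture`, i.e. kilograms (= litres) of
#' soil water under one square metre of ground. Used to express solution
#' concentrations as areal availability.
#'
#' @param soil A [soil_state()].
#' @return Litres of soil water per m2 of ground.
#' @examples
#' soil_water_volume(soil_state(7, 6, 25)) # 90 L/m2
#' @export
soil_water_volume <- function(soil) {
  stopifnot(inherits(soil, "soil_state"))
  soil$profile_depth * soil$bulk_density * soil$moisture
}

#' Areal availability of Si(OH)4
#'
#' Bioavailable concentration times the soil water volume, in mg of Si(OH)4
#' per m2 of ground -- the quantity a response surface over pH and organic
#' matter is naturally drawn in.
#'
#' @inheritParams available_si
#' @return mg/m2 Si(OH)4.
#' @examples
#' areal_availability(soil_state(7, 6, 25, si_water = 5)) # ~8567 mg/m2
#' @export
areal_availability <- function(soil, params = availability_params(),
                               include_irrigation = TRUE) {
  available_si(soil, params, include_irrigation) * soil_water_volume(soil)
}

#' Areal availability over a pH x organic-matter grid
#'
#' @param ph Monotone vector of pH values (grid rows).
#' @param om Monotone vector of organic-matter values, % w/w (grid columns).
#' @param soil_temperature Soil temperature, degC, fixed over the grid.
#' @param soil A [soil_state()] providing the remaining fields (depth,
#'   moisture, bulk density, irrigation Si).
#' @param params An [availability_params()].
#' @return A numeric matrix (mg/m2) with `dimnames` giving the pH and OM
#'   coordinates and attributes `ph`, `om`, `soil_temperature`.
#' @export
availability_grid <- function(ph, om, soil_temperature,
                              soil = soil_state(7, 0, soil_temperature),
                              params = availability_params()) {
  if (length(ph) < 1L || length(om) < 1L) {
    si_abort("availability_grid() needs non-empty ph and om ranges")
  }
  if (is.unsorted(ph, strictly = FALSE) && is.unsorted(rev(ph))) {
    si_abort("ph coordinates must be monotone")
  }
  if (is.unsorted(om, strictly = FALSE) && is.unsorted(rev(om))) {
    si_abort("om coordinates must be monotone")
  }
  vol <- soil_water_volume(soil)
  e_t <- temperature_effect(soil_temperature, params)
  conc <- outer(
    ph_effect(ph, params), om_effect(om, params),
    function(p, o) (params$si_p - soil$si_water) * e_t * p * o + soil$si_water
  )
  g <- pmin(conc, params$si_p) * vol
  dimnames(g) <- list(ph = format(ph), om = format(om))
  attr(g, "ph") <- ph
  attr(g, "om") <- om
  attr(g, "soil_temperature") <- soil_temperature
  g
}
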
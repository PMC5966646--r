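# Transpiration-stream silicon accumulation.
#
# Silicon enters the plant dissolved as Si(OH)4 in the transpiration
# stream; once polymerized in tissue it stays for the life of the plant,
# so the account is monotone. Bookkeeping is in grams of SiO2 per m2 of
# ground (the form results are reported in); conversion from the dissolved
# Si(OH)4 uses the chem_units stoichiometry. Accumulation is capped each
# step at 1% of the current dry biomass (as SiO2), and each (possibly
# truncated) increment is split over organs by their transpiration shares:
# leaves 90%, stem 5%, fruit 2.5%, root 2.5%.

#' Silicon uptake parameters
#'
#' @param si_si Fraction of transpiration-stream Si retained by the plant,
#'   in `[0, 1]`. Default 1 (pure transpiration-stream uptake, cap-limited).
#' @param max_si_fraction Saturation cap as a fraction of dry biomass held
#'   as SiO2. Default 0.01 (1%).
#' @param organ_transpiration_fractions Named shares (leaf, stem, fruit,
#'   root) of whole-plant transpiration, summing to 1.
#' @param pd Planting density, plants/m2 (converts per-area to per-plant).
#' @return A list of class `uptake_params`.
#' @export
uptake_params <- function(si_si = 1, max_si_fraction = 0.01,
                          organ_transpiration_fractions =
                            c(leaf = 0.90, stem = 0.05, fruit = 0.025, root = 0.025),
                          pd = 3) {
  if (!is.numeric(si_si) || si_si < 0 || si_si > 1) {
    si_abort("si_si must lie in [0, 1]")
  }
  stopifnot(max_si_fraction > 0, pd > 0)
  f <- organ_transpiration_fractions
  if (!identical(names(f), c("leaf", "stem", "fruit", "root")) ||
      any(f < 0) || abs(sum(f) - 1) > 1e-12) {
    si_abort("organ transpiration fractions must be named leaf/stem/fruit/root, >= 0, and sum to exactly 1")
  }
  structure(
    list(
      si_si = si_si, max_si_fraction = max_si_fraction,
      organ_transpiration_fractions = f, pd = pd
    ),
    class = "uptake_params"
  )
}

#' Create a silicon account
#'
#' @param organ_si Named vector (leaf, stem, fruit, root) of accumulated
#'   SiO2, g/m2.
#' @return A list of class `si_account` with fields `total_si` and
#'   `organ_si`.
#' @export
si_account <- function(organ_si = c(leaf = 0, stem = 0, fruit = 0, root = 0)) {
  if (!identical(names(organ_si), c("leaf", "stem", "fruit", "root")) ||
      any(organ_si < 0)) {
    si_abort("organ_si must be a non-negative vector named leaf/stem/fruit/root")
  }
  structure(
    list(total_si = sum(organ_si), organ_si = organ_si),
    class = "si_account"
  )
}

#' Maximum silicon capacity of the standing crop
#'
#' One percent of dry biomass held as SiO2, per unit ground area. The
#' per-plant figure is the result divided by planting density.
#'
#' @param biomass_total Dry biomass, g/m2 (vectorized).
#' @param params An [uptake_params()] object.
#' @return g SiO2 per m2.
#' @examples
#' max_si_capacity(4110) / 3 # 13.7 g SiO2 per plant at 3 plants/m2
#' @export
max_si_capacity <- function(biomass_total, params = uptake_params()) {
  stopifnot(is.numeric(biomass_total), all(biomass_total >= 0))
  params$max_si_fraction * biomass_total
}

#' Split a silicon increment over organs by transpiration share
#'
#' @param increment SiO2 mass to allocate, g/m2 (>= 0).
#' @param params An [uptake_params()] object.
#' @return Named vector (leaf, stem, fruit, root) summing to `increment`.
#' @examples
#' allocate_organs(10) # leaf 9, stem 0.5, fruit 0.25, root 0.25
#' @export
allocate_organs <- function(increment, params = uptake_params()) {
  if (!is.numeric(increment) || increment < 0) {
    si_abort("increment must be >= 0")
  }
  increment * params$organ_transpiration_fractions
}

# mass ratio converting dissolved Si(OH)4 to deposited SiO2 (~0.625)
.sioh4_to_sio2 <- function() {
  si_species("SiO2")$molar_mass / si_species("SiOH4")$molar_mass
}

#' Accumulate silicon over one transpiration interval
#'
#' The increment is `concentration x volume x si_si`, converted from mg of
#' Si(OH)4 to g of SiO2, then truncated so the running total never exceeds
#' the capacity implied by the current biomass. Soil cultivation feeds the
#' soil-solution availability here; soilless cultivation feeds the
#' irrigation-water concentration -- same operation, different source.
#'
#' @param account An [si_account()].
#' @param si_concentration Si(OH)4 concentration of the absorbed water,
#'   mg/L.
#' @param transpired_volume Water transpired over the interval, L/m2.
#' @param cap Current capacity from [max_si_capacity()], g SiO2/m2.
#' @param params An [uptake_params()] object.
#' @return The updated `si_account`.
#' @export
uptake_step <- function(account, si_concentration, transpired_volume, cap,
                        params = uptake_params()) {
  stopifnot(inherits(account, "si_account"))
  if (si_concentration < 0 || transpired_volume < 0 || cap < 0) {
    si_abort("uptake_step() inputs must be >= 0")
  }
  inc <- si_concentration * transpired_volume * params$si_si / 1000 *
    .sioh4_to_sio2()
  inc <- max(0, min(inc, cap - account$total_si))
  si_account(account$organ_si + allocate_organs(inc, params))
}

#' Whole-plant silicon concentration
#'
#' @param account An [si_account()].
#' @param biomass_total Dry biomass, g/m2 (> 0).
#' @return Percent of dry weight held as SiO2; `<= 100 * max_si_fraction`
#'   whenever the cap has been respected.
#' @export
si_concentration_pct <- function(account, biomass_total) {
  stopifnot(inherits(account, "si_account"))
  if (!is.numeric(biomass_total) || biomass_total <= 0) {
    si_abort("silicon concentration is undefined at zero biomass")
  }
  100 * account$total_si / biomass_total
}
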
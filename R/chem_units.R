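# Silicate species and concentration-unit conversions.
#
# Every concentration that crosses a module boundary is a `si_conc` value
# object carrying its unit and chemical species, because "mg/L Si" and
# "mg/L Si(OH)4" differ by a factor of ~3.4 and are routinely confused in
# the agronomic literature.

# Atomic masses (g/mol) used throughout; conversions between the printed
# literature values and these masses agree within 2% (the literature's own
# rounding is inconsistent).
SI_ATOMIC_MASS <- c(Si = 28.086, O = 15.999, H = 1.008, Na = 22.990)

.si_species_table <- local({
  m <- SI_ATOMIC_MASS
  data.frame(
    name = c("Si", "SiOH4", "SiO2", "Na2SiO3"),
    molar_mass = c(
      m[["Si"]],
      m[["Si"]] + 4 * (m[["O"]] + m[["H"]]),
      m[["Si"]] + 2 * m[["O"]],
      2 * m[["Na"]] + m[["Si"]] + 3 * m[["O"]]
    ),
    si_atoms = c(1L, 1L, 1L, 1L),
    stringsAsFactors = FALSE
  )
})

#' Look up a silicate species
#'
#' Returns the molar mass and Si stoichiometry of one of the supported
#' silicate species: elemental Si, orthosilicic acid `"SiOH4"`, silica
#' `"SiO2"`, or (anhydrous) sodium metasilicate `"Na2SiO3"`.
#'
#' @param name Species name, one of `"Si"`, `"SiOH4"`, `"SiO2"`, `"Na2SiO3"`.
#' @return A list with elements `name`, `molar_mass` (g/mol) and
#'   `si_atoms` (Si atoms per formula unit).
#' @examples
#' si_species("SiOH4")$molar_mass # ~96.11 g/mol
#' @export
si_species <- function(name) {
  i <- match(name, .si_species_table$name)
  if (length(name) != 1L || is.na(i)) {
    si_abort(
      sprintf(
        "unsupported silicate species '%s'; supported: %s",
        toString(name), toString(.si_species_table$name)
      ),
      class = "silicrop_unsupported_species"
    )
  }
  as.list(.si_species_table[i, ])
}

#' Create a silicon concentration value object
#'
#' @param value Non-negative numeric scalar.
#' @param unit `"mg_per_L"` or `"mM"`.
#' @param species Species name (see [si_species()]).
#' @return An object of class `si_conc`.
#' @examples
#' si_conc(1.8, "mM", "SiOH4")
#' @export
si_conc <- function(value, unit = c("mg_per_L", "mM"), species = "SiOH4") {
  unit <- match.arg(unit)
  sp <- si_species(species)
  if (!is.numeric(value) || length(value) != 1L || !is.finite(value)) {
    si_abort("concentration value must be a finite numeric scalar")
  }
  if (value < 0) {
    si_abort("concentration value must be >= 0")
  }
  structure(
    list(value = as.numeric(value), unit = unit, species = sp$name),
    class = "si_conc"
  )
}

#' @export
print.si_conc <- function(x, ...) {
  unit_lbl <- if (x$unit == "mg_per_L") "mg/L" else "mM"
  cat(sprintf("<si_conc> %g %s %s\n", x$value, unit_lbl, x$species))
  invisible(x)
}

# millimoles of Si per litre implied by a si_conc
.si_mmol_per_L <- function(conc) {
  sp <- si_species(conc$species)
  if (conc$unit == "mM") {
    conc$value * sp$si_atoms
  } else {
    conc$value / sp$molar_mass * sp$si_atoms
  }
}

#' Convert a silicon concentration between units and species
#'
#' Conversion conserves moles of Si: expressing a concentration "as" a
#' different species answers "what concentration of the target species
#' carries the same amount of silicon".
#'
#' @param conc An [si_conc()] object.
#' @param unit Target unit (defaults to the current unit).
#' @param species Target species (defaults to the current species).
#' @return A new `si_conc` in the target unit/species.
#' @examples
#' si_convert(si_conc(1.8, "mM", "SiOH4"), "mg_per_L") # ~173 mg/L
#' si_convert(si_conc(28, "mg_per_L", "Si"), "mg_per_L", "SiOH4") # ~96 mg/L
#' @export
si_convert <- function(conc, unit = NULL, species = NULL) {
  stopifnot(inherits(conc, "si_conc"))
  unit <- if (is.null(unit)) conc$unit else match.arg(unit, c("mg_per_L", "mM"))
  species <- if (is.null(species)) conc$species else species
  sp <- si_species(species)
  mmol_si <- .si_mmol_per_L(conc)
  mmol_sp <- mmol_si / sp$si_atoms
  value <- if (unit == "mM") mmol_sp else mmol_sp * sp$molar_mass
  si_conc(value, unit, species)
}

#' Classify an orthosilicic-acid concentration against solubility thresholds
#'
#' Si(OH)4 stays monomeric (plant-available) up to about 1.8 mM; at 2 mM it
#' condenses into hydrated amorphous silica polymers that plants cannot take
#' up. The band between the two is reported as `"at_threshold"`.
#'
#' @param conc An [si_conc()] expressed as species `"SiOH4"` (any unit).
#' @return One of `"soluble"` (< 1.8 mM), `"at_threshold"` (1.8-2 mM),
#'   `"polymerizing"` (>= 2 mM).
#' @examples
#' polymerization_status(si_conc(0.5, "mM", "SiOH4"))
#' @export
polymerization_status <- function(conc) {
  stopifnot(inherits(conc, "si_conc"))
  if (conc$species != "SiOH4") {
    si_abort("polymerization_status() requires a Si(OH)4 concentration; convert first")
  }
  mm <- si_convert(conc, "mM")$value
  if (mm < 1.8) "soluble" else if (mm < 2.0) "at_threshold" else "polymerizing"
}

# internal: condition helper shared by all modules
si_abort <- function(message, class = "silicrop_validation_error", call = NULL) {
  stop(structure(
    class = c(class, "silicrop_error", "error", "condition"),
    list(message = message, call = call)
  ))
}
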
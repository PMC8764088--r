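#' Physical constants for the supported trace gases
#'
#' Per-species constants used throughout the package: the mass of the
#' reported element carried by one mole of gas (carbon for CH4, the two
#' nitrogen atoms for N2O) and the length of the reporting year.
#'
#' @param species `"CH4"` or `"N2O"`.
#' @param element_mass Grams of reported element per mole of gas. Defaults:
#'   CH4-C 12.011 g, N2O-N 28.014 g (2 x 14.007, IUPAC 2021).
#' @param seconds_per_year Seconds in the reporting year; default 3.15576e7
#'   (365.25 d).
#'
#' @return A list of class `species_constants` with fields `species`,
#'   `element_mass` and `seconds_per_year`.
#' @examples
#' species_constants("N2O")
#' @export
species_constants <- function(species,
                              element_mass = NULL,
                              seconds_per_year = 3.15576e7) {
  species <- match_species(species)
  if (is.null(element_mass)) {
    element_mass <- switch(species, CH4 = 12.011, N2O = 2 * 14.007)
  }
  stopifnot(is.numeric(element_mass), element_mass > 0,
            is.numeric(seconds_per_year), seconds_per_year > 0)
  structure(
    list(species = species, element_mass = element_mass,
         seconds_per_year = seconds_per_year),
    class = "species_constants"
  )
}

match_species <- function(species) {
  if (length(species) != 1L || !is.character(species) ||
      !(species %in% c("CH4", "N2O"))) {
    stop("`species` must be one of \"CH4\", \"N2O\"", call. = FALSE)
  }
  species
}

#' Convert an instantaneous area flux to an annual element-mass flux
#'
#' Converts nmol (gas) m^-2 s^-1 to kg (element) ha^-1 yr^-1: CH4 fluxes are
#' reported as CH4-C, N2O fluxes as N2O-N. The sign is preserved
#' (micrometeorological convention: negative = uptake).
#'
#' @param flux Flux in nmol m^-2 s^-1 (vectorised).
#' @param species `"CH4"` or `"N2O"`, or a [species_constants()] object.
#'
#' @return Flux in kg element ha^-1 yr^-1.
#' @examples
#' nmol_to_annual(1, "CH4")   # 3.7906 kg CH4-C ha^-1 yr^-1
#' @export
nmol_to_annual <- function(flux, species) {
  k <- as_species_constants(species)
  stopifnot(is.numeric(flux), all(is.finite(flux)))
  flux * 1e-9 * k$element_mass * k$seconds_per_year * 1e4 / 1e3
}

#' Convert an annual element-mass flux back to an instantaneous area flux
#'
#' Exact inverse of [nmol_to_annual()].
#'
#' @inheritParams nmol_to_annual
#' @param flux Flux in kg element ha^-1 yr^-1 (vectorised).
#' @return Flux in nmol m^-2 s^-1.
#' @export
annual_to_nmol <- function(flux, species) {
  k <- as_species_constants(species)
  stopifnot(is.numeric(flux), all(is.finite(flux)))
  flux * 1e3 / (1e-9 * k$element_mass * k$seconds_per_year * 1e4)
}

as_species_constants <- function(species) {
  if (inherits(species, "species_constants")) species
  else species_constants(species)
}

#' @export
print.species_constants <- function(x, ...) {
  cat(sprintf("<species_constants> %s: %.4g g element mol^-1, %.6g s yr^-1\n",
              x$species, x$element_mass, x$seconds_per_year))
  invisible(x)
}
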
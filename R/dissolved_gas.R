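#' Henry solubility parameters
#'
#' Temperature-dependent Henry solubility in the van't Hoff form
#' `kH(T) = kH_298 * exp(vant_hoff * (1/T - 1/298.15))`. Defaults follow the
#' common solubility compilations: CH4 kH_298 = 1.4e-3 mol L^-1 atm^-1 with
#' van't Hoff coefficient 1750 K; N2O kH_298 = 2.4e-2 with 2700 K. Both are
#' overrideable since lab protocols differ in the constants they adopt.
#'
#' @param species `"CH4"` or `"N2O"`.
#' @param kH_298 Henry solubility at 298.15 K, mol L^-1 atm^-1.
#' @param vant_hoff Temperature coefficient d(ln kH)/d(1/T), K.
#' @return A list of class `solubility_params`.
#' @examples
#' solubility_params("CH4")
#' @export
solubility_params <- function(species, kH_298 = NULL, vant_hoff = NULL) {
  species <- match_species(species)
  if (is.null(kH_298)) kH_298 <- switch(species, CH4 = 1.4e-3, N2O = 2.4e-2)
  if (is.null(vant_hoff)) vant_hoff <- switch(species, CH4 = 1750, N2O = 2700)
  if (kH_298 <= 0) stop("`kH_298` must be > 0", call. = FALSE)
  if (vant_hoff <= 0) stop("`vant_hoff` must be > 0", call. = FALSE)
  structure(list(species = species, kH_298 = kH_298, vant_hoff = vant_hoff),
            class = "solubility_params")
}

as_solubility_params <- function(params, species = NULL) {
  if (inherits(params, "solubility_params")) params
  else solubility_params(species %||% params)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Henry solubility at a given temperature
#'
#' @param params A [solubility_params()].
#' @param temperature Water temperature in K. Values outside (263, 323) K
#'   raise an extrapolation warning.
#' @return Henry solubility in mol L^-1 atm^-1.
#' @examples
#' henry_constant(solubility_params("CH4"), 288.15)
#' @export
henry_constant <- function(params, temperature) {
  params <- as_solubility_params(params)
  stopifnot(is.numeric(temperature), all(is.finite(temperature)),
            all(temperature > 0))
  if (any(temperature <= 263 | temperature >= 323)) {
    warning("temperature outside (263, 323) K: extrapolating the van't Hoff fit",
            call. = FALSE)
  }
  params$kH_298 * exp(params$vant_hoff * (1 / temperature - 1 / 298.15))
}

#' Stream-water headspace-equilibration vial
#'
#' One vial record from the headspace equilibration technique: a known
#' volume of bubble-free stream water injected into an N2-pre-flushed vial,
#' shaken to equilibrium, and the headspace mole fraction measured.
#'
#' @param species `"CH4"` or `"N2O"`.
#' @param water_volume Water volume in mL (protocol: 6).
#' @param headspace_volume Headspace volume in mL (12 mL vial minus water).
#' @param equilibration_temperature Temperature at equilibration, K.
#' @param headspace_mole_fraction Measured headspace mole fraction,
#'   nmol mol^-1.
#' @param initial_headspace_mole_fraction Mole fraction in the headspace
#'   before equilibration; 0 for N2-flushed vials (default).
#' @param lab_pressure Laboratory pressure in atm (default 1).
#' @return A list of class `vial_sample`.
#' @export
vial_sample <- function(species, water_volume = 6, headspace_volume = 6,
                        equilibration_temperature = 298.15,
                        headspace_mole_fraction = 0,
                        initial_headspace_mole_fraction = 0,
                        lab_pressure = 1) {
  species <- match_species(species)
  if (water_volume <= 0 || headspace_volume <= 0) {
    stop("vial volumes must be > 0", call. = FALSE)
  }
  if (headspace_mole_fraction < 0 || initial_headspace_mole_fraction < 0) {
    stop("mole fractions must be >= 0", call. = FALSE)
  }
  if (equilibration_temperature <= 0) stop("temperature must be > 0 K",
                                           call. = FALSE)
  if (lab_pressure <= 0) stop("pressure must be > 0 atm", call. = FALSE)
  structure(
    list(species = species, water_volume = water_volume,
         headspace_volume = headspace_volume,
         equilibration_temperature = equilibration_temperature,
         headspace_mole_fraction = headspace_mole_fraction,
         initial_headspace_mole_fraction = initial_headspace_mole_fraction,
         lab_pressure = lab_pressure),
    class = "vial_sample"
  )
}

#' Original dissolved gas concentration from an equilibrated vial
#'
#' Inverts the two-compartment equilibrium: at equilibrium the gas partial
#' pressure is `p = x_hs * P`; the headspace holds `n_hs = p V_hs / (R T)`
#' moles and the water `n_aq = kH(T) p V_w`. Any gas present in the
#' headspace before equilibration is subtracted, and the remainder is
#' attributed to the injected stream water:
#' `C = (n_hs + n_aq - n_init) / V_w`.
#'
#' @param vial A [vial_sample()].
#' @param params A [solubility_params()]; defaults to the species defaults.
#' @return A list of class `dissolved_result` with `concentration_molar`
#'   (mol L^-1), `concentration_mass` (ug element L^-1: C for CH4, N for
#'   N2O) and the vial's species.
#' @examples
#' v <- vial_sample("CH4", headspace_mole_fraction = 5000)
#' headspace_to_dissolved(v)
#' @export
headspace_to_dissolved <- function(vial, params = NULL) {
  stopifnot(inherits(vial, "vial_sample"))
  params <- as_solubility_params(params %||% vial$species)
  kH <- henry_constant(params, vial$equilibration_temperature)
  p <- vial$headspace_mole_fraction * 1e-9 * vial$lab_pressure      # atm
  v_hs <- vial$headspace_volume / 1000                              # L
  v_w <- vial$water_volume / 1000                                   # L
  n_hs <- p * v_hs / (GAS_CONSTANT_L_ATM * vial$equilibration_temperature)
  n_aq <- kH * p * v_w
  p0 <- vial$initial_headspace_mole_fraction * 1e-9 * vial$lab_pressure
  n_init <- p0 * v_hs / (GAS_CONSTANT_L_ATM * vial$equilibration_temperature)
  conc <- (n_hs + n_aq - n_init) / v_w
  if (conc < 0) {
    stop("recovered dissolved concentration is negative: ",
         "inconsistent vial inputs", call. = FALSE)
  }
  k <- species_constants(vial$species)
  structure(
    list(species = vial$species, concentration_molar = conc,
         concentration_mass = conc * k$element_mass * 1e6),
    class = "dissolved_result"
  )
}

#' @export
print.dissolved_result <- function(x, ...) {
  cat(sprintf("<dissolved_result> %s: %.4g mol L^-1 (%.4g ug element L^-1)\n",
              x$species, x$concentration_molar, x$concentration_mass))
  invisible(x)
}

#' Dissolved concentration at equilibrium with the atmosphere
#'
#' The reference concentration a stream would hold if it were in Henry's-law
#' equilibrium with the ambient atmosphere. Reported per litre on either an
#' element-mass basis (ug C L^-1 for CH4, ug N L^-1 for N2O; the default) or
#' a full-molecule mass basis -- published reference values differ in which
#' basis they use, so both are supported.
#'
#' @param species `"CH4"` or `"N2O"`.
#' @param temperature Stream temperature in K.
#' @param atm_mixing_ratio Atmospheric mixing ratio in nmol mol^-1. Defaults:
#'   1870 ppb CH4, 332 ppb N2O (circa the late-2010s atmosphere).
#' @param params Optional [solubility_params()].
#' @param mass_basis `"element"` (default) or `"molecule"` (16.043 g for
#'   CH4, 44.013 g for N2O).
#' @return Equilibrium concentration in ug L^-1 on the chosen basis.
#' @examples
#' equilibrium_concentration("CH4", 298.15)  # ~0.03 ug C L^-1
#' @export
equilibrium_concentration <- function(species, temperature,
                                      atm_mixing_ratio = NULL,
                                      params = NULL,
                                      mass_basis = c("element", "molecule")) {
  species <- match_species(species)
  mass_basis <- match.arg(mass_basis)
  if (is.null(atm_mixing_ratio)) {
    atm_mixing_ratio <- switch(species, CH4 = 1870, N2O = 332)
  }
  stopifnot(atm_mixing_ratio >= 0)
  params <- as_solubility_params(params %||% species)
  mass <- switch(mass_basis,
                 element = species_constants(species)$element_mass,
                 molecule = switch(species, CH4 = 16.043, N2O = 44.013))
  henry_constant(params, temperature) * atm_mixing_ratio * 1e-9 * mass * 1e6
}

#' Saturation ratio relative to atmospheric equilibrium
#'
#' Ratio of a measured dissolved concentration to the equilibrium
#' concentration at the stream temperature; values above 1 denote
#' supersaturation (the stream outgasses to the atmosphere).
#'
#' @param result A [headspace_to_dissolved()] result, or a bare
#'   concentration in ug element L^-1.
#' @param species `"CH4"` or `"N2O"` (taken from `result` when available).
#' @param stream_temperature Stream temperature in K.
#' @param atm_mixing_ratio Atmospheric mixing ratio, nmol mol^-1.
#' @param params Optional [solubility_params()].
#' @return Dimensionless saturation ratio.
#' @export
saturation_ratio <- function(result, species = NULL,
                             stream_temperature = 298.15,
                             atm_mixing_ratio = NULL, params = NULL) {
  if (inherits(result, "dissolved_result")) {
    conc <- result$concentration_mass
    species <- result$species
  } else {
    conc <- result
    species <- match_species(species)
  }
  stopifnot(conc >= 0)
  eq <- equilibrium_concentration(species, stream_temperature,
                                  atm_mixing_ratio, params)
  if (eq <= 0) stop("equilibrium concentration is zero; ratio undefined",
                    call. = FALSE)
  conc / eq
}
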
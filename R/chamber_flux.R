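# Ideal gas constant in L atm K^-1 mol^-1, as used in field protocols.
GAS_CONSTANT_L_ATM <- 0.08206

#' Chamber geometry
#'
#' Describes the headspace volume and soil footprint of a flux chamber.
#' Static soil chambers are cylinders sealed to the soil surface; floating
#' chambers sit on the water surface during inundation.
#'
#' @param volume Headspace volume in litres; must be positive.
#' @param area Enclosed surface area in m^2; must be positive. Floating
#'   chambers rarely report a footprint, so the static default
#'   `pi * 0.15^2` m^2 is used unless given.
#' @param kind `"static"` or `"floating"`.
#' @return A list of class `chamber_geometry`.
#' @seealso [chamber_geometry_from_dimensions()] for cylindrical chambers.
#' @examples
#' chamber_geometry(volume = 17, area = pi * 0.15^2, kind = "floating")
#' @export
chamber_geometry <- function(volume, area = pi * 0.15^2,
                             kind = c("static", "floating")) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(volume), length(volume) == 1L, is.finite(volume),
            is.numeric(area), length(area) == 1L, is.finite(area))
  if (volume <= 0) stop("chamber `volume` must be > 0", call. = FALSE)
  if (area <= 0) stop("chamber `area` must be > 0", call. = FALSE)
  structure(list(volume = volume, area = area, kind = kind),
            class = "chamber_geometry")
}

#' Cylindrical chamber geometry from diameter and height
#'
#' @param diameter,height Chamber diameter and height in metres (the common
#'   field design is d = h = 0.30 m).
#' @param kind Passed to [chamber_geometry()].
#' @return A `chamber_geometry` with `volume = pi (d/2)^2 h` (in litres) and
#'   `area = pi (d/2)^2` (in m^2).
#' @examples
#' chamber_geometry_from_dimensions(0.30, 0.30)
#' @export
chamber_geometry_from_dimensions <- function(diameter, height,
                                             kind = "static") {
  stopifnot(diameter > 0, height > 0)
  r <- diameter / 2
  chamber_geometry(volume = pi * r^2 * height * 1000,
                   area = pi * r^2, kind = kind)
}

#' @export
print.chamber_geometry <- function(x, ...) {
  cat(sprintf("<chamber_geometry> %s: V = %.3f L, S = %.5f m^2\n",
              x$kind, x$volume, x$area))
  invisible(x)
}

#' Headspace concentration time series for one chamber closure
#'
#' One static-chamber deployment: the gas mole fraction in the chamber
#' headspace sampled at a few time points after closure (canonically 0, 20,
#' 40 and 60 min), with the headspace temperature recorded at each point.
#'
#' @param chamber_id Identifier for the chamber.
#' @param species `"CH4"` or `"N2O"`.
#' @param times Minutes since closure; strictly increasing, length >= 2.
#' @param mole_fractions Dry-air mole fractions in nmol mol^-1 (ppb);
#'   non-negative.
#' @param temperatures Headspace temperatures in K, one per time point
#'   (a single value is recycled).
#' @param pressure Ambient pressure in atm (default 1).
#' @return A list of class `headspace_series`.
#' @export
headspace_series <- function(chamber_id, species, times, mole_fractions,
                             temperatures, pressure = 1) {
  species <- match_species(species)
  n <- length(times)
  if (length(temperatures) == 1L) temperatures <- rep(temperatures, n)
  if (n < 2L) stop("a headspace series needs at least 2 time points",
                   call. = FALSE)
  if (length(mole_fractions) != n || length(temperatures) != n) {
    stop("`times`, `mole_fractions` and `temperatures` must have equal length",
         call. = FALSE)
  }
  if (any(diff(times) <= 0)) {
    stop("`times` must be strictly increasing", call. = FALSE)
  }
  if (any(temperatures <= 0)) stop("`temperatures` must be > 0 K",
                                   call. = FALSE)
  if (any(mole_fractions < 0)) stop("`mole_fractions` must be >= 0",
                                    call. = FALSE)
  if (pressure <= 0) stop("`pressure` must be > 0 atm", call. = FALSE)
  structure(
    list(chamber_id = chamber_id, species = species,
         times = as.numeric(times), mole_fractions = as.numeric(mole_fractions),
         temperatures = as.numeric(temperatures), pressure = pressure),
    class = "headspace_series"
  )
}

#' @export
print.headspace_series <- function(x, ...) {
  cat(sprintf("<headspace_series> chamber %s, %s, %d points over %g min\n",
              x$chamber_id, x$species, length(x$times), max(x$times)))
  invisible(x)
}

#' Ordinary least-squares slope of headspace concentration against time
#'
#' Fits mole fraction (ppb) against minutes since closure by OLS and returns
#' the slope converted to per-second units together with the coefficient of
#' determination of the fit. A two-point series has R^2 defined as 1; a
#' constant (zero-variance) series returns slope 0 and R^2 = 0 so that its
#' zero flux is kept rather than discarded.
#'
#' @param series A [headspace_series()].
#' @return A list with `slope` (nmol mol^-1 s^-1) and `r_squared`.
#' @examples
#' s <- headspace_series("c1", "N2O", c(0, 20, 40, 60),
#'                       c(330, 350, 370, 390), 298.15)
#' fit_concentration_slope(s)
#' @export
fit_concentration_slope <- function(series) {
  stopifnot(inherits(series, "headspace_series"))
  t_min <- series$times
  y <- series$mole_fractions
  n <- length(t_min)
  if (stats::var(y) == 0) {
    return(list(slope = 0, r_squared = 0))
  }
  fit <- stats::lm(y ~ t_min)
  slope_min <- unname(stats::coef(fit)[["t_min"]])
  # R^2 computed directly: summary.lm warns on exact-line series
  r2 <- if (n == 2L) 1 else
    1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)
  list(slope = slope_min / 60, r_squared = r2)
}

#' Total moles of gas in a chamber headspace
#'
#' Ideal gas law n = PV/RT with R = 0.08206 L atm K^-1 mol^-1.
#'
#' @param geometry A [chamber_geometry()].
#' @param temperature Headspace temperature in K.
#' @param pressure Ambient pressure in atm.
#' @return Moles of gas in the headspace.
#' @examples
#' chamber_moles(chamber_geometry(22.414, 1), 273.15, 1)  # ~1 mol
#' @export
chamber_moles <- function(geometry, temperature, pressure = 1) {
  stopifnot(inherits(geometry, "chamber_geometry"))
  if (!is.finite(temperature) || temperature <= 0) {
    stop("`temperature` must be > 0 K", call. = FALSE)
  }
  if (!is.finite(pressure) || pressure <= 0) {
    stop("`pressure` must be > 0 atm", call. = FALSE)
  }
  pressure * geometry$volume / (GAS_CONSTANT_L_ATM * temperature)
}

#' Soil-atmosphere flux from a chamber closure
#'
#' Combines the OLS concentration slope with the chamber gas inventory
#' (n = PV/RT) and footprint: F = slope x n / S in nmol m^-2 s^-1, under the
#' micrometeorological sign convention (negative = uptake). Closures failing
#' the R^2 quality check are flagged, never discarded: low R^2 is mostly
#' associated with near-zero fluxes and dropping them would bias the record
#' towards high fluxes.
#'
#' @param series A [headspace_series()].
#' @param geometry A [chamber_geometry()].
#' @param temperature How to pick the temperature entering n = PV/RT:
#'   `"mean"` (default, arithmetic mean over the closure) or `"first"`.
#' @param qc_threshold R^2 above which a fit passes quality control
#'   (strict inequality; default 0.95).
#' @return A list of class `flux_estimate` with fields `chamber_id`,
#'   `species`, `flux` (nmol m^-2 s^-1), `slope` (nmol mol^-1 s^-1),
#'   `r_squared`, `n_points`, `qc_pass`, `retained` (always `TRUE`).
#' @examples
#' geom <- chamber_geometry_from_dimensions(0.30, 0.30)
#' s <- headspace_series("c1", "N2O", c(0, 20, 40, 60),
#'                       c(330, 350, 370, 390), 298.15)
#' compute_flux(s, geom)
#' @export
compute_flux <- function(series, geometry,
                         temperature = c("mean", "first"),
                         qc_threshold = 0.95) {
  temperature <- match.arg(temperature)
  stopifnot(inherits(series, "headspace_series"),
            inherits(geometry, "chamber_geometry"))
  fit <- fit_concentration_slope(series)
  t_k <- switch(temperature,
                mean = mean(series$temperatures),
                first = series$temperatures[[1L]])
  n_tot <- chamber_moles(geometry, t_k, series$pressure)
  # slope [nmol mol^-1 s^-1] * n_tot [mol] / S [m^2] -> nmol m^-2 s^-1
  flux <- fit$slope * n_tot / geometry$area
  structure(
    list(chamber_id = series$chamber_id, species = series$species,
         flux = flux, slope = fit$slope, r_squared = fit$r_squared,
         n_points = length(series$times),
         qc_pass = fit$r_squared > qc_threshold, retained = TRUE),
    class = "flux_estimate"
  )
}

#' @export
print.flux_estimate <- function(x, ...) {
  cat(sprintf(
    "<flux_estimate> chamber %s %s: %.4g nmol m^-2 s^-1 (R^2 = %.3f, QC %s)\n",
    x$chamber_id, x$species, x$flux, x$r_squared,
    if (x$qc_pass) "pass" else "fail"))
  invisible(x)
}

#' Compute fluxes for every closure in a chamber-series table
#'
#' Groups a long-format table (as read by [read_chamber_table()]) by
#' `chamber_id` and `species` and applies [compute_flux()] to each group.
#'
#' @param tab Data frame with columns `chamber_id`, `species`, `time_min`,
#'   `mole_fraction_ppb`, `temp_C` and optionally `pressure_atm`.
#' @inheritParams compute_flux
#' @return Data frame with one row per closure and the `flux_estimate`
#'   fields as columns.
#' @export
compute_flux_table <- function(tab, geometry,
                               temperature = c("mean", "first"),
                               qc_threshold = 0.95) {
  temperature <- match.arg(temperature)
  needed <- c("chamber_id", "species", "time_min", "mole_fraction_ppb",
              "temp_C")
  missing <- setdiff(needed, names(tab))
  if (length(missing)) {
    stop("missing columns: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  if (is.null(tab$pressure_atm)) tab$pressure_atm <- 1
  keys <- unique(tab[, c("chamber_id", "species")])
  out <- lapply(seq_len(nrow(keys)), function(i) {
    g <- tab[tab$chamber_id == keys$chamber_id[i] &
               tab$species == keys$species[i], ]
    g <- g[order(g$time_min), ]
    s <- headspace_series(keys$chamber_id[i], keys$species[i], g$time_min,
                          g$mole_fraction_ppb, g$temp_C + 273.15,
                          g$pressure_atm[[1L]])
    est <- compute_flux(s, geometry, temperature, qc_threshold)
    as.data.frame(est[c("chamber_id", "species", "flux", "slope",
                        "r_squared", "n_points", "qc_pass", "retained")])
  })
  do.call(rbind, out)
}
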
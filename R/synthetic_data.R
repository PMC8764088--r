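# Run expr with a private RNG stream derived from (seed, generator name),
# restoring the caller's RNG state afterwards. The salt decouples the
# streams of different generators so composed pipelines are reproducible
# regardless of call order.
with_generator_seed <- function(seed, salt, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  h <- sum(utf8ToInt(salt) * seq_along(utf8ToInt(salt)))
  derived <- as.integer((abs(seed) + 1000003 * h) %% 2147483647)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(derived)
  force(expr)
}

#' Simulation specification for one chamber closure
#'
#' @param true_flux True flux in nmol m^-2 s^-1.
#' @param geometry A [chamber_geometry()]; default the d = h = 0.30 m
#'   static chamber.
#' @param species `"CH4"` or `"N2O"`.
#' @param x0 Initial mole fraction, ppb.
#' @param times Sampling times in minutes.
#' @param temperature Headspace temperature, K.
#' @param pressure Ambient pressure, atm.
#' @param noise_sd Gaussian measurement noise on the mole fractions, ppb.
#' @param curvature Optional time constant tau (min) of exponential
#'   flattening, emulating saturating accumulation; `NULL` for linear.
#' @param seed Integer seed.
#' @return A list of class `chamber_sim_spec`.
#' @export
chamber_sim_spec <- function(true_flux, geometry = NULL, species = "N2O",
                             x0 = 330, times = c(0, 20, 40, 60),
                             temperature = 298.15, pressure = 1,
                             noise_sd = 0, curvature = NULL, seed = 1) {
  if (is.null(geometry)) geometry <- chamber_geometry_from_dimensions(0.3, 0.3)
  stopifnot(inherits(geometry, "chamber_geometry"), noise_sd >= 0)
  structure(
    list(true_flux = true_flux, geometry = geometry,
         species = match_species(species), x0 = x0, times = times,
         temperature = temperature, pressure = pressure,
         noise_sd = noise_sd, curvature = curvature, seed = seed),
    class = "chamber_sim_spec"
  )
}

#' Generate a synthetic chamber headspace series
#'
#' Inverts the flux computation: a flux `F` over footprint `S` adds
#' `F * S * t / n` to the headspace mole fraction (n = PV/RT), giving a
#' linear rise plus independent Gaussian noise; with `curvature` set, the
#' rise flattens as `slope * tau * (1 - exp(-t / tau))`. Deterministic
#' under a fixed seed.
#'
#' @param spec A [chamber_sim_spec()].
#' @param chamber_id Identifier for the generated series.
#' @return A [headspace_series()].
#' @examples
#' s <- generate_chamber_series(chamber_sim_spec(0.2044, seed = 7))
#' compute_flux(s, chamber_geometry_from_dimensions(0.3, 0.3))$flux
#' @export
generate_chamber_series <- function(spec, chamber_id = "sim") {
  stopifnot(inherits(spec, "chamber_sim_spec"))
  n_tot <- chamber_moles(spec$geometry, spec$temperature, spec$pressure)
  slope_ppb_s <- spec$true_flux * spec$geometry$area / n_tot
  t_s <- spec$times * 60
  x <- if (is.null(spec$curvature)) {
    spec$x0 + slope_ppb_s * t_s
  } else {
    tau_s <- spec$curvature * 60
    spec$x0 + slope_ppb_s * tau_s * (1 - exp(-t_s / tau_s))
  }
  if (spec$noise_sd > 0) {
    x <- with_generator_seed(spec$seed, "chamber_series",
                             x + stats::rnorm(length(x), 0, spec$noise_sd))
  }
  # strong uptake can drive the series below zero from a low baseline; lift
  # the whole series instead of clipping (the flux only sees the slope)
  if (min(x) < 0) x <- x - min(x)
  headspace_series(chamber_id, spec$species, spec$times, x,
                   rep(spec$temperature, length(spec$times)), spec$pressure)
}

#' Simulation specification for a flux panel
#'
#' Embodies the variance structure the mixed models assume: on the log
#' scale of the flux magnitude, independent Gaussian random intercepts for
#' plot, chamber and date plus residual noise, and optional linear
#' temperature and WFPS effects on centred covariates.
#'
#' @param forest_type Label for the generated panel.
#' @param true_median Geometric-mean (median) flux magnitude on the
#'   reporting scale; its sign is taken from `sign_regime`.
#' @param sd_chamber,sd_date,sd_residual Log-scale SDs of the chamber and
#'   date random intercepts and the residual (defaults 0.4, 0.3, 0.5).
#' @param sd_plot Log-scale SD of the plot intercept (default 0).
#' @param n_chambers,n_plots,n_dates Design size (defaults 5, 1, 52).
#' @param beta_temp,beta_wfps Log-scale slopes per degC / per % WFPS.
#' @param temp_range,wfps_range Uniform sampling ranges for the covariates.
#' @param sign_regime `"positive"`, `"negative"` (all fluxes negated) or
#'   `"mixed"` (fluxes are `exp(log-magnitude) - shift`, requiring
#'   `shift > 0`).
#' @param shift Offset for the mixed regime.
#' @param site Site label.
#' @param start_date First sampling date; dates step weekly.
#' @param seed Integer seed.
#' @return A list of class `panel_sim_spec`.
#' @export
panel_sim_spec <- function(forest_type = "lowland", true_median = 1.56,
                           sd_chamber = 0.4, sd_date = 0.3,
                           sd_residual = 0.5, sd_plot = 0,
                           n_chambers = 5, n_plots = 1, n_dates = 52,
                           beta_temp = 0, beta_wfps = 0,
                           temp_range = c(20, 28), wfps_range = c(30, 90),
                           sign_regime = c("positive", "negative", "mixed"),
                           shift = 0, site = "site1",
                           start_date = as.Date("2018-01-01"), seed = 1) {
  sign_regime <- match.arg(sign_regime)
  stopifnot(true_median != 0, sd_chamber >= 0, sd_date >= 0,
            sd_residual >= 0, sd_plot >= 0,
            n_chambers >= 1, n_plots >= 1, n_dates >= 1)
  if (sign_regime == "mixed" && shift <= 0) {
    stop("`sign_regime = \"mixed\"` requires a positive `shift`",
         call. = FALSE)
  }
  if (sign_regime == "negative" && true_median > 0) {
    true_median <- -true_median
  }
  structure(
    list(forest_type = forest_type, true_median = true_median,
         sd_chamber = sd_chamber, sd_date = sd_date,
         sd_residual = sd_residual, sd_plot = sd_plot,
         n_chambers = n_chambers, n_plots = n_plots, n_dates = n_dates,
         beta_temp = beta_temp, beta_wfps = beta_wfps,
         temp_range = temp_range, wfps_range = wfps_range,
         sign_regime = sign_regime, shift = shift, site = site,
         start_date = as.Date(start_date), seed = seed),
    class = "panel_sim_spec"
  )
}

#' Generate a synthetic flux panel
#'
#' Simulates `log|flux| = log|median| + b_plot + b_chamber + b_date +
#' beta_t (T - T_mid) + beta_w (W - W_mid) + eps`, with independent
#' zero-mean Gaussian effects at the specified SDs and covariates drawn
#' uniformly in their ranges, then applies the sign regime. Chambers are
#' assigned to plots round-robin and dates step weekly.
#'
#' @param spec A [panel_sim_spec()].
#' @return A flux panel data frame (`site`, `forest_type`, `plot`,
#'   `chamber_id`, `date`, `week`, `flux`, `soil_temperature`, `wfps`,
#'   `inundated`) with a `units` attribute.
#' @export
generate_flux_panel <- function(spec) {
  stopifnot(inherits(spec, "panel_sim_spec"))
  with_generator_seed(spec$seed, "flux_panel", {
    plots <- paste0("p", rep_len(seq_len(spec$n_plots), spec$n_chambers))
    chambers <- paste0("c", seq_len(spec$n_chambers))
    dates <- spec$start_date + 7 * (seq_len(spec$n_dates) - 1)
    b_plot <- stats::rnorm(spec$n_plots, 0, spec$sd_plot)
    b_ch <- stats::rnorm(spec$n_chambers, 0, spec$sd_chamber)
    b_date <- stats::rnorm(spec$n_dates, 0, spec$sd_date)
    g <- expand.grid(chamber = seq_len(spec$n_chambers),
                     date = seq_len(spec$n_dates))
    n <- nrow(g)
    temp <- stats::runif(n, spec$temp_range[1], spec$temp_range[2])
    wfps <- stats::runif(n, spec$wfps_range[1], spec$wfps_range[2])
    logmag <- log(abs(spec$true_median)) +
      b_plot[rep_len(seq_len(spec$n_plots), spec$n_chambers)][g$chamber] +
      b_ch[g$chamber] + b_date[g$date] +
      spec$beta_temp * (temp - mean(spec$temp_range)) +
      spec$beta_wfps * (wfps - mean(spec$wfps_range)) +
      stats::rnorm(n, 0, spec$sd_residual)
    flux <- switch(spec$sign_regime,
                   positive = exp(logmag),
                   negative = -exp(logmag),
                   mixed = exp(logmag) - spec$shift)
    panel <- data.frame(
      site = spec$site, forest_type = spec$forest_type,
      plot = plots[g$chamber], chamber_id = chambers[g$chamber],
      date = dates[g$date], week = iso_week(dates[g$date]),
      flux = flux, soil_temperature = temp, wfps = wfps,
      inundated = FALSE, stringsAsFactors = FALSE)
    attr(panel, "units") <- "kg_element_ha_yr"
    panel
  })
}

#' Generate a synthetic stream equilibration vial
#'
#' Solves the two-compartment Henry's-law mole balance for the headspace
#' mole fraction an N2-flushed vial would show after equilibration with
#' water of a known dissolved concentration, then adds Gaussian
#' measurement noise. Exact inverse of [headspace_to_dissolved()] at zero
#' noise.
#'
#' @param true_conc True dissolved concentration, ug element L^-1.
#' @param species `"CH4"` or `"N2O"`.
#' @param water_volume,headspace_volume Vial partition, mL.
#' @param temperature Equilibration temperature, K.
#' @param params Optional [solubility_params()].
#' @param lab_pressure Laboratory pressure, atm.
#' @param noise_sd Gaussian noise on the headspace mole fraction, ppb.
#' @param seed Integer seed.
#' @return A [vial_sample()].
#' @export
generate_stream_sample <- function(true_conc, species = "CH4",
                                   water_volume = 6, headspace_volume = 6,
                                   temperature = 298.15, params = NULL,
                                   lab_pressure = 1, noise_sd = 0,
                                   seed = 1) {
  stopifnot(true_conc >= 0, noise_sd >= 0)
  species <- match_species(species)
  params <- as_solubility_params(params %||% species)
  k <- species_constants(species)
  conc_molar <- true_conc * 1e-6 / k$element_mass
  v_w <- water_volume / 1000
  v_hs <- headspace_volume / 1000
  kH <- henry_constant(params, temperature)
  n_tot <- conc_molar * v_w
  # n_tot = x P (V_hs/(RT) + kH V_w)  =>  solve for x (in mole fraction)
  x <- n_tot / (lab_pressure *
                  (v_hs / (GAS_CONSTANT_L_ATM * temperature) + kH * v_w))
  x_ppb <- x * 1e9
  if (noise_sd > 0) {
    x_ppb <- with_generator_seed(seed, "stream_sample",
                                 x_ppb + stats::rnorm(1, 0, noise_sd))
  }
  vial_sample(species, water_volume, headspace_volume, temperature,
              headspace_mole_fraction = max(x_ppb, 0),
              initial_headspace_mole_fraction = 0,
              lab_pressure = lab_pressure)
}

#' Generate synthetic isotope chamber pairs by forward mixing
#'
#' Mixes a known amount of source N2O with fixed source deltas into a
#' background pool and records the resulting start/end concentrations and
#' deltas, exercising the mixing-model inversion and the minimum-increase
#' filter (amounts below 31 ppb are included deliberately).
#'
#' @param background List with `c0` (ppb) and background deltas `d15n`,
#'   `d18o`, optionally `d15n_alpha`, `d15n_beta` (permil).
#' @param source List of source deltas with the same names.
#' @param added_amounts Numeric vector of added N2O, ppb (>= 0).
#' @param seed Integer seed (reserved for future noise; generation is
#'   currently exact).
#' @return Data frame of isotope pairs, one row per added amount.
#' @export
generate_isotope_pairs <- function(background = list(c0 = 330, d15n = 6.7,
                                                     d18o = 44.6),
                                   source = list(d15n = -20, d18o = 20),
                                   added_amounts = c(10, 30, 31, 100),
                                   seed = 1) {
  stopifnot(all(added_amounts >= 0), background$c0 > 0)
  mix_fwd <- function(d0, ds, a) {
    if (is.null(d0) || is.null(ds)) return(rep(NA_real_, length(a)))
    (background$c0 * d0 + a * ds) / (background$c0 + a)
  }
  a <- added_amounts
  data.frame(
    chamber_id = paste0("iso", seq_along(a)),
    c_start = background$c0, c_end = background$c0 + a,
    d15n_start = background$d15n %||% NA_real_,
    d15n_end = mix_fwd(background$d15n, source$d15n, a),
    d18o_start = background$d18o %||% NA_real_,
    d18o_end = mix_fwd(background$d18o, source$d18o, a),
    d15n_alpha_start = background$d15n_alpha %||% NA_real_,
    d15n_alpha_end = mix_fwd(background$d15n_alpha, source$d15n_alpha, a),
    d15n_beta_start = background$d15n_beta %||% NA_real_,
    d15n_beta_end = mix_fwd(background$d15n_beta, source$d15n_beta, a),
    stringsAsFactors = FALSE)
}
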
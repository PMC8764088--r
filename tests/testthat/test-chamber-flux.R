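geom30 <- chamber_geometry_from_dimensions(0.30, 0.30)

series <- function(x, t = c(0, 20, 40, 60), temp = 298.15, ...) {
  headspace_series("c1", "N2O", t, x, temp, ...)
}

test_that("cylindrical geometry constructor gives pi r^2 h volume and footprint", {
  expect_equal(geom30$volume, pi * 0.15^2 * 0.30 * 1000)
  expect_equal(geom30$area, pi * 0.15^2)
  expect_error(chamber_geometry(volume = -1, area = 1), "volume")
  expect_error(chamber_geometry(volume = 1, area = 0), "area")
})

test_that("series constructor enforces ordering, lengths and positivity", {
  expect_error(series(c(1, 2, 3, 4), t = c(0, 20, 20, 60)), "increasing")
  expect_error(series(c(1, 2, 3)), "equal length")
  expect_error(series(c(-1, 2, 3, 4)), ">= 0")
  expect_error(series(c(1, 2, 3, 4), temp = -5), "> 0 K")
  expect_error(headspace_series("c", "N2O", 0, 330, 298), "at least 2")
})

test_that("constant, exact-line and noisy series give the documented slopes", {
  const <- fit_concentration_slope(series(rep(330, 4)))
  expect_equal(const$slope, 0)
  expect_equal(const$r_squared, 0)

  line <- fit_concentration_slope(series(c(330, 350, 370, 390)))
  expect_equal(line$slope, 1 / 60)
  expect_equal(line$r_squared, 1)

  noisy <- series(c(330, 348, 372, 390))
  got <- fit_concentration_slope(noisy)
  want <- ols_oracle(noisy$times, noisy$mole_fractions)
  expect_equal(got$slope, want$slope / 60, tolerance = 1e-12)
  expect_equal(got$r_squared, want$r_squared, tolerance = 1e-12)

  two <- fit_concentration_slope(series(c(330, 350), t = c(0, 20)))
  expect_equal(two$r_squared, 1)
})

test_that("chamber gas inventory follows n = PV/RT", {
  expect_equal(chamber_moles(chamber_geometry(22.414, 1), 273.15, 1),
               1 / (0.08206 * 273.15) * 22.414)
  expect_equal(round(chamber_moles(chamber_geometry(22.414, 1), 273.15, 1), 4),
               1.0000, tolerance = 1e-3)
  # hand evaluation of PV/RT for the d = h = 0.30 m chamber at 25 degC
  expect_equal(chamber_moles(geom30, 298.15, 1),
               1 * 21.205750411731103 / (0.08206 * 298.15),
               tolerance = 1e-9)
  expect_error(chamber_moles(geom30, 298.15, 0), "pressure")
  expect_error(chamber_moles(geom30, -1, 1), "temperature")
})

test_that("a 1 ppb/min rise in the 30 cm chamber gives ~0.2044 nmol m^-2 s^-1", {
  est <- compute_flux(series(c(330, 350, 370, 390)), geom30)
  # oracle: (1 ppb/min -> n_tot * 1e-9 / 60 mol s^-1) / S, in nmol
  n_tot <- 21.205750411731103 / (0.08206 * 298.15)
  expect_equal(est$flux, (n_tot / 60) / (pi * 0.15^2), tolerance = 1e-12)
  expect_equal(round(est$flux, 4), 0.2044)
  expect_true(est$qc_pass)
  expect_true(est$retained)
})

test_that("constant series yields zero flux, QC failure, and retention", {
  est <- compute_flux(series(rep(330, 4)), geom30)
  expect_equal(est$flux, 0)
  expect_false(est$qc_pass)
  expect_true(est$retained)
})

test_that("noise-free synthetic series round-trip to the true flux", {
  for (phi in c(-6, -0.5, 0, 0.01, 1, 50, 3000)) {
    s <- generate_chamber_series(chamber_sim_spec(phi, seed = 1))
    est <- compute_flux(s, geom30)
    if (phi == 0) expect_equal(est$flux, 0)
    else expect_lt(abs(est$flux - phi) / abs(phi), 1e-10)
  }
})

test_that("flux is linear in slope, inverse in area, and offset-invariant", {
  base <- compute_flux(series(c(330, 350, 370, 390)), geom30)
  doubled <- compute_flux(series(c(330, 370, 410, 450)), geom30)
  expect_equal(doubled$flux, 2 * base$flux, tolerance = 1e-12)

  half_area <- chamber_geometry(geom30$volume, geom30$area / 2)
  expect_equal(compute_flux(series(c(330, 350, 370, 390)), half_area)$flux,
               2 * base$flux, tolerance = 1e-12)

  shifted <- compute_flux(series(c(330, 350, 370, 390) + 500), geom30)
  expect_equal(shifted$flux, base$flux, tolerance = 1e-12)

  falling <- compute_flux(series(c(390, 370, 350, 330)), geom30)
  expect_lt(falling$flux, 0)
  expect_equal(sign(falling$flux), sign(falling$slope))
})

test_that("slope and R^2 agree with the normal-equations oracle on random series", {
  set.seed(401)
  for (i in 1:1000) {
    y <- 330 + cumsum(runif(4, -5, 20)) + rnorm(4, 0, 3)
    s <- series(pmax(y, 0))
    got <- fit_concentration_slope(s)
    want <- ols_oracle(s$times, s$mole_fractions)
    expect_equal(got$slope, want$slope / 60, tolerance = 1e-10)
    expect_lt(abs(got$r_squared - want$r_squared), 1e-9)
  }
})

test_that("QC threshold is a strict inequality and configurable", {
  est <- compute_flux(series(c(330, 348, 372, 390)), geom30)
  expect_true(est$r_squared > 0.95)
  strict <- compute_flux(series(c(330, 348, 372, 390)), geom30,
                         qc_threshold = est$r_squared)
  expect_false(strict$qc_pass)
})

test_that("mean vs first-point temperature choice moves the flux as n = PV/RT", {
  s <- headspace_series("c1", "N2O", c(0, 20, 40, 60),
                        c(330, 350, 370, 390), c(293.15, 295.15, 297.15, 299.15))
  est_mean <- compute_flux(s, geom30, temperature = "mean")
  est_first <- compute_flux(s, geom30, temperature = "first")
  expect_equal(est_mean$flux / est_first$flux, 293.15 / 296.15,
               tolerance = 1e-12)
})

test_that("table interface reproduces per-series fluxes", {
  tab <- data.frame(
    chamber_id = rep(c("a", "b"), each = 4), species = "N2O",
    time_min = rep(c(0, 20, 40, 60), 2),
    mole_fraction_ppb = c(330, 350, 370, 390, 400, 398, 395, 391),
    temp_C = 25)
  out <- compute_flux_table(tab, geom30)
  expect_equal(nrow(out), 2)
  expect_equal(out$flux[out$chamber_id == "a"],
               compute_flux(series(c(330, 350, 370, 390)), geom30)$flux)
  expect_lt(out$flux[out$chamber_id == "b"], 0)
})
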
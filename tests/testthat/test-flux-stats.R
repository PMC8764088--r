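test_that("WFPS conversion divides by porosity", {
  expect_equal(wfps_from_vwc(0, 1.3), 0)
  expect_equal(wfps_from_vwc(0.30, 1.325), 60)  # porosity 0.5
  expect_equal(wfps_from_vwc(1 - 1.325 / 2.65, 1.325), 100)  # saturation
  expect_error(wfps_from_vwc(0.3, 2.65), "porosity")
  expect_error(wfps_from_vwc(0.3, 3.0), "porosity")
})

test_that("between-chamber variability summarises chamber averages", {
  p <- make_panel(flux = c(1, 1, 2, 2, 3, 3),
                  chamber_id = rep(c("a", "b", "c"), each = 2),
                  date = rep(c("2018-01-01", "2018-01-08"), 3))
  v <- between_chamber_variability(p)
  expect_equal(v$variance, 1)
  expect_equal(v$sd, 1)
  expect_equal(v$cv, 0.5)

  same <- make_panel(flux = rep(2, 6),
                     chamber_id = rep(c("a", "b", "c"), each = 2),
                     date = rep(c("2018-01-01", "2018-01-08"), 3))
  expect_equal(between_chamber_variability(same)$variance, 0)

  shuffled <- p[sample(nrow(p)), ]
  expect_equal(between_chamber_variability(shuffled), v)

  expect_error(between_chamber_variability(p[p$chamber_id == "a", ]),
               ">= 2 chambers")
})

test_that("intra-annual variability pools weeks across years", {
  p <- make_panel(flux = c(1, 1, 2, 2, 3, 3), chamber_id = "a",
                  date = c("2018-01-01", "2019-01-02",   # both ISO week 1
                           "2018-01-08", "2019-01-09",   # week 2
                           "2018-01-15", "2019-01-16"))  # week 3
  v <- intra_annual_variability(p)
  expect_equal(v$n, 3)
  expect_equal(v$variance, 1)
  expect_equal(v$cv, 0.5)
  expect_error(intra_annual_variability(p[1:2, ]), ">= 2 weeks")
})

test_that("percent change transform matches (exp(x) - 1) * 100", {
  expect_equal(percent_change(0), 0)
  expect_equal(percent_change(log(2)), 100)
  expect_equal(percent_change(-0.10536), -10.0, tolerance = 1e-4)
})

test_that("transform specs validate their domains and invert exactly", {
  p <- generate_flux_panel(panel_sim_spec(true_median = 2, seed = 5))
  expect_error(fit_geometric_mean_model(
    transform(p, flux = -flux), transform_spec("log_positive")),
    "non-positive")
  expect_error(fit_geometric_mean_model(p, transform_spec("negate_log")),
               "all-negative")
  expect_error(fit_geometric_mean_model(
    p, transform_spec("shifted_log", shift = -1e6)), "shift")
})

test_that("a constant panel returns the constant with zero variance", {
  p <- make_panel(flux = rep(2.5, 12),
                  chamber_id = rep(c("a", "b", "c"), 4),
                  date = rep(c("2018-01-01", "2018-01-08",
                               "2018-01-15", "2018-01-22"), each = 3))
  m <- fit_geometric_mean_model(p, transform_spec("log_positive"))
  expect_equal(m$geometric_mean, 2.5)
  expect_equal(m$ci_low, 2.5)
  expect_equal(m$ci_high, 2.5)
  expect_true(all(m$variance_components == 0))
})

test_that("with zero group variance the intercept SE hits the closed form", {
  # residuals built so every chamber mean and every date mean equals the
  # grand mean: the REML variance components collapse to zero and the
  # intercept SE must equal the log-scale sample-mean SE
  e <- seq(-0.5, 0.5, length.out = 20)
  e <- e - mean(e)
  p <- make_panel(flux = exp(log(2) + c(e, -e)),
                  chamber_id = rep(c("a", "b"), each = 20),
                  date = rep(as.character(as.Date("2018-01-01") +
                                            7 * (0:19)), 2))
  m <- fit_geometric_mean_model(p, transform_spec("log_positive"))
  y <- log(p$flux)
  expect_true(m$singular)
  expect_equal(m$intercept, mean(y), tolerance = 1e-8)
  expect_equal(m$intercept_se, sqrt(var(y) / length(y)), tolerance = 1e-4)
})

test_that("the geometric-mean estimator recovers the simulation truth", {
  gms <- vapply(1:30, function(i) {
    p <- generate_flux_panel(panel_sim_spec(
      true_median = 1.56, n_chambers = 5, n_dates = 26, seed = 1000 + i))
    fit_geometric_mean_model(p, transform_spec("log_positive"))$geometric_mean
  }, numeric(1))
  expect_lt(abs(mean(gms) - 1.56) / 1.56, 0.10)
})

test_that("negate_log back-transform restores the uptake sign", {
  spec <- panel_sim_spec(true_median = 3.52, sign_regime = "negative",
                         n_dates = 26, seed = 21)
  p <- generate_flux_panel(spec)
  expect_true(all(p$flux < 0))
  m <- fit_geometric_mean_model(p, transform_spec("negate_log"))
  expect_lt(m$geometric_mean, 0)
  expect_true(m$ci_low <= m$geometric_mean && m$geometric_mean <= m$ci_high)
  # equals the negated fit on the magnitudes
  p_mag <- transform(p, flux = -flux)
  m_mag <- fit_geometric_mean_model(p_mag, transform_spec("log_positive"))
  expect_equal(m$geometric_mean, -m_mag$geometric_mean, tolerance = 1e-9)
})

test_that("shifted_log estimates translate with the panel", {
  spec <- panel_sim_spec(true_median = 2, sign_regime = "mixed", shift = 3,
                         n_dates = 26, seed = 31)
  p <- generate_flux_panel(spec)
  expect_true(any(p$flux < 0) && any(p$flux > 0))
  m1 <- fit_geometric_mean_model(p, transform_spec("shifted_log", shift = 3))
  k <- 1.7
  p2 <- transform(p, flux = flux + k)
  m2 <- fit_geometric_mean_model(p2,
                                 transform_spec("shifted_log", shift = 3 - k))
  expect_equal(m2$geometric_mean, m1$geometric_mean + k, tolerance = 1e-6)
})

test_that("plot nesting is used when the panel has multiple plots", {
  spec <- panel_sim_spec(true_median = 2, n_chambers = 6, n_plots = 2,
                         sd_plot = 0.3, n_dates = 26, seed = 41)
  p <- generate_flux_panel(spec)
  m <- fit_geometric_mean_model(p, transform_spec("log_positive"))
  expect_true(all(c("plot", "chamber", "date", "residual") %in%
                    names(m$variance_components)))
  expect_true(all(m$variance_components >= 0))
})

test_that("driver model recovers a known temperature effect as % change", {
  spec <- panel_sim_spec(true_median = 2, beta_temp = 0.05,
                         n_chambers = 5, n_dates = 150, seed = 3)
  p <- generate_flux_panel(spec)
  m <- fit_driver_model(p, transform_spec("log_positive"))
  fe <- m$fixed_effects
  row <- fe[fe$term == "soil_temperature", ]
  # truth (exp(0.05) - 1) * 100 = 5.127 %, within 3 SEs of the fit
  expect_lt(abs(row$estimate - 0.05), 3 * row$se)
  expect_equal(row$percent_change, percent_change(row$estimate))
  expect_true(row$ci_low_pct < 5.127 & 5.127 < row$ci_high_pct)
})

test_that("null covariate effects are covered by their CIs at ~nominal rate", {
  covered <- vapply(1:120, function(i) {
    p <- generate_flux_panel(panel_sim_spec(
      true_median = 2, n_chambers = 5, n_dates = 30, seed = 5000 + i))
    fe <- fit_driver_model(p, transform_spec("log_positive"))$fixed_effects
    row <- fe[fe$term == "wfps", ]
    row$ci_low_pct <= 0 && 0 <= row$ci_high_pct
  }, logical(1))
  expect_gte(mean(covered), 0.90)
})

test_that("a single-chamber panel reduces to ordinary regression", {
  spec <- panel_sim_spec(true_median = 2, n_chambers = 1, sd_chamber = 0,
                         beta_temp = 0.05, n_dates = 60, seed = 51)
  p <- generate_flux_panel(spec)
  m <- fit_driver_model(p, transform_spec("log_positive"))
  ref <- lm(log(flux) ~ soil_temperature + wfps, data = p)
  expect_equal(m$fixed_effects$estimate[m$fixed_effects$term ==
                                          "soil_temperature"],
               unname(coef(ref)[["soil_temperature"]]), tolerance = 1e-9)
})

test_that("constant covariates are flagged non-estimable, not fitted", {
  p <- generate_flux_panel(panel_sim_spec(true_median = 2, n_dates = 20,
                                          seed = 61))
  p$wfps <- 50
  expect_warning(m <- fit_driver_model(p, transform_spec("log_positive")),
                 "non-estimable")
  fe <- m$fixed_effects
  expect_false(fe$estimable[fe$term == "wfps"])
  expect_true(is.na(fe$estimate[fe$term == "wfps"]))
})

test_that("Nakagawa-Schielzeth R2 partitions the plug-in variances", {
  p0 <- generate_flux_panel(panel_sim_spec(true_median = 2, n_dates = 30,
                                           seed = 71))
  m0 <- fit_geometric_mean_model(p0, transform_spec("log_positive"))
  expect_equal(m0$r2_marginal, 0)
  expect_gte(m0$r2_conditional, m0$r2_marginal)
  expect_lte(m0$r2_conditional, 1)

  spec <- panel_sim_spec(true_median = 2, sd_chamber = 0.4, sd_date = 0,
                         sd_residual = 0.5, beta_temp = 0.1,
                         n_chambers = 10, n_dates = 100, seed = 81)
  p <- generate_flux_panel(spec)
  m <- fit_driver_model(p, transform_spec("log_positive"))
  var_f <- 0.1^2 * (28 - 20)^2 / 12      # uniform covariate variance
  want <- var_f / (var_f + 0.4^2 + 0.5^2)
  expect_equal(m$r2_marginal, want, tolerance = 0.06)
  expect_gte(m$r2_conditional, m$r2_marginal)
})

test_that("forest-type summary splits swamp by inundation state", {
  pn <- generate_flux_panel(panel_sim_spec("swamp", true_median = 2.68,
                                           n_dates = 20, seed = 91))
  pi_ <- generate_flux_panel(panel_sim_spec("swamp", true_median = 341,
                                            n_dates = 20, seed = 92))
  pi_$inundated <- TRUE
  pl <- generate_flux_panel(panel_sim_spec("lowland", true_median = 1.56,
                                           n_dates = 20, seed = 93))
  panel <- rbind(pn, pi_, pl)
  s <- summarize_by_forest_type(panel)
  expect_setequal(s$forest_type,
                  c("swamp_non_inundated", "swamp_inundated", "lowland"))
  expect_gt(s$point[s$forest_type == "swamp_inundated"], 100)
  expect_true(all(s$ci_low <= s$point & s$point <= s$ci_high))
})
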
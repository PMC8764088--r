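#' Convert volumetric water content to water-filled pore space
#'
#' WFPS is the volumetric water content expressed as a percentage of total
#' soil porosity, `100 * vwc / (1 - bulk_density / particle_density)`.
#'
#' @param vwc Volumetric water content, m^3 m^-3 (in \[0, 1\]).
#' @param bulk_density Soil bulk density, g cm^-3.
#' @param particle_density Particle density, g cm^-3; the mineral-soil
#'   default is 2.65.
#' @return WFPS in percent (vectorised over `vwc`).
#' @examples
#' wfps_from_vwc(0.30, 1.325)  # 60 %
#' @export
wfps_from_vwc <- function(vwc, bulk_density, particle_density = 2.65) {
  stopifnot(is.numeric(vwc), all(vwc >= 0), all(vwc <= 1))
  if (bulk_density <= 0 || bulk_density >= particle_density) {
    stop("`bulk_density` must be in (0, particle_density): ",
         "porosity would be non-positive", call. = FALSE)
  }
  porosity <- 1 - bulk_density / particle_density
  100 * vwc / porosity
}

check_flux_panel <- function(panel) {
  needed <- c("site", "forest_type", "chamber_id", "date", "flux")
  missing <- setdiff(needed, names(panel))
  if (length(missing)) {
    stop("flux panel is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(panel$wfps) && any(panel$wfps < 0 | panel$wfps > 150,
                                  na.rm = TRUE)) {
    stop("`wfps` outside [0, 150] %", call. = FALSE)
  }
  invisible(panel)
}

summarise_dispersion <- function(x) {
  v <- stats::var(x)
  m <- mean(x)
  list(variance = v, sd = sqrt(v),
       cv = if (m == 0) NA_real_ else sqrt(v) / abs(m), n = length(x))
}

#' Between-chamber variability of a flux panel
#'
#' Averages the fluxes of each chamber over the monitoring period, then
#' reports the sample variance, standard deviation and coefficient of
#' variation across those chamber averages.
#'
#' @param panel Flux panel data frame (columns `site`, `forest_type`,
#'   `chamber_id`, `date`, `flux`, optionally `plot`, `week`, covariates).
#' @return List with `variance`, `sd`, `cv` (sd over the absolute mean of
#'   the chamber averages) and `n` (number of chambers).
#' @export
between_chamber_variability <- function(panel) {
  check_flux_panel(panel)
  means <- tapply(panel$flux, panel$chamber_id, mean)
  if (length(means) < 2L) {
    stop("between-chamber variability needs >= 2 chambers", call. = FALSE)
  }
  summarise_dispersion(as.numeric(means))
}

#' Intra-annual variability of a flux panel
#'
#' Pools observations into weekly classes irrespective of sampling year,
#' averages per week, and reports the dispersion of the weekly site means.
#'
#' @inheritParams between_chamber_variability
#' @return List with `variance`, `sd`, `cv` and `n` (number of weeks).
#' @export
intra_annual_variability <- function(panel) {
  check_flux_panel(panel)
  week <- panel$week
  if (is.null(week)) week <- iso_week(panel$date)
  means <- tapply(panel$flux, week, mean)
  if (length(means) < 2L) {
    stop("intra-annual variability needs >= 2 weeks", call. = FALSE)
  }
  summarise_dispersion(as.numeric(means))
}

# ISO-8601 week number of a calendar date.
iso_week <- function(date) as.integer(format(as.Date(date), "%V"))

#' Log-transform specification for flux responses
#'
#' Soil-gas fluxes are strongly right-skewed and are modelled on the log
#' scale, but uptake fluxes are negative, so the transform must be an
#' explicit, recorded choice: `log_positive` (plain log; errors on any
#' non-positive flux), `negate_log` (log of the magnitudes of an
#' all-negative panel; the back-transform restores the sign) or
#' `shifted_log` (`log(flux + shift)` for mixed-sign panels).
#'
#' @param method `"log_positive"`, `"negate_log"` or `"shifted_log"`.
#' @param shift Offset for `shifted_log`; must exceed `-min(flux)`.
#' @return A list of class `transform_spec`.
#' @export
transform_spec <- function(method = c("log_positive", "negate_log",
                                      "shifted_log"),
                           shift = 0) {
  method <- match.arg(method)
  structure(list(method = method, shift = shift), class = "transform_spec")
}

apply_transform <- function(flux, spec) {
  switch(spec$method,
    log_positive = {
      if (any(flux <= 0)) {
        stop("log_positive transform on non-positive fluxes (records: ",
             paste(utils::head(which(flux <= 0), 5L), collapse = ", "),
             "); choose negate_log or shifted_log", call. = FALSE)
      }
      log(flux)
    },
    negate_log = {
      if (any(flux >= 0)) {
        stop("negate_log transform requires an all-negative panel (records: ",
             paste(utils::head(which(flux >= 0), 5L), collapse = ", "), ")",
             call. = FALSE)
      }
      log(-flux)
    },
    shifted_log = {
      if (any(flux + spec$shift <= 0)) {
        stop("shifted_log: `shift` must exceed -min(flux)", call. = FALSE)
      }
      log(flux + spec$shift)
    }
  )
}

invert_transform <- function(y, spec) {
  switch(spec$method,
    log_positive = exp(y),
    negate_log = -exp(y),
    shifted_log = exp(y) - spec$shift
  )
}

# Extract named variance components from a merMod fit; groups whose name
# contains "chamber"/"plot"/"date" map onto those roles.
varcomp_table <- function(fit) {
  vc <- lme4::VarCorr(fit)
  comps <- vapply(vc, function(m) m[1, 1], numeric(1))
  c(comps, residual = stats::sigma(fit)^2)
}

role_of <- function(nm) {
  if (grepl("chamber", nm)) "chamber"
  else if (grepl("plot", nm)) "plot"
  else if (grepl("date", nm)) "date"
  else nm
}

#' Geometric mean flux via a log-scale mixed model
#'
#' Fits, by REML, an intercept-only linear mixed model to the transformed
#' fluxes of one forest type, with chamber nested in plot and sampling date
#' as crossed random intercepts:
#' `y ~ 1 + (1 | plot) + (1 | plot:chamber) + (1 | date)` (the plot level is
#' collapsed when the panel has fewer than two plots). The exponentiated
#' intercept is the geometric mean flux -- the distribution's median under
#' lognormality -- and the 95% interval is Wald on the transformed scale
#' (`intercept +- 1.96 SE`), both mapped back through the inverse of the
#' chosen transform (including its sign or shift).
#'
#' @param panel Flux panel restricted to one forest type.
#' @param transform A [transform_spec()].
#' @return A list of class `mixed_model_result`: `intercept`, `intercept_se`
#'   (transformed scale), `geometric_mean`, `ci_low`, `ci_high` (natural
#'   scale), `variance_components` (named: plot/chamber/date/residual),
#'   `fixed_effects` (data frame), `var_fixed`, `r2_marginal`,
#'   `r2_conditional`, `n_obs`, `n_chambers`, `n_dates`, `singular`,
#'   `transform`, and the underlying `fit`.
#' @examples
#' panel <- generate_flux_panel(panel_sim_spec(true_median = 2, seed = 1))
#' fit_geometric_mean_model(panel, transform_spec("log_positive"))
#' @export
fit_geometric_mean_model <- function(panel,
                                     transform = transform_spec("log_positive")) {
  check_flux_panel(panel)
  if (length(unique(panel$forest_type)) > 1L) {
    stop("fit one forest type at a time", call. = FALSE)
  }
  stopifnot(inherits(transform, "transform_spec"))
  d <- data.frame(
    y = apply_transform(panel$flux, transform),
    plot = factor(if (is.null(panel$plot)) panel$site else panel$plot),
    chamber = factor(panel$chamber_id),
    date = factor(panel$date)
  )
  if (stats::var(d$y) == 0) {
    # Degenerate constant panel: the geometric mean is the constant itself.
    return(finish_mixed_result(
      intercept = d$y[[1L]], intercept_se = 0,
      comps = c(plot = 0, chamber = 0, date = 0, residual = 0),
      fixed = data.frame(term = "(Intercept)", estimate = d$y[[1L]],
                         se = 0, percent_change = NA_real_),
      var_fixed = 0, d = d, transform = transform, singular = TRUE,
      fit = NULL))
  }
  form <- if (nlevels(d$plot) > 1L) {
    y ~ 1 + (1 | plot) + (1 | plot:chamber) + (1 | date)
  } else {
    y ~ 1 + (1 | chamber) + (1 | date)
  }
  fit <- lme4::lmer(form, data = d, REML = TRUE,
                    control = lme4::lmerControl(calc.derivs = FALSE))
  sm <- summary(fit)$coefficients
  finish_mixed_result(
    intercept = sm["(Intercept)", "Estimate"],
    intercept_se = sm["(Intercept)", "Std. Error"],
    comps = varcomp_table(fit),
    fixed = data.frame(term = "(Intercept)",
                       estimate = sm["(Intercept)", "Estimate"],
                       se = sm["(Intercept)", "Std. Error"],
                       percent_change = NA_real_),
    var_fixed = 0, d = d, transform = transform,
    singular = lme4::isSingular(fit), fit = fit)
}

finish_mixed_result <- function(intercept, intercept_se, comps, fixed,
                                var_fixed, d, transform, singular, fit) {
  names(comps) <- vapply(names(comps), role_of, character(1))
  ci <- sort(invert_transform(
    intercept + c(-1, 1) * 1.96 * intercept_se, transform))
  res <- structure(
    list(intercept = intercept, intercept_se = intercept_se,
         geometric_mean = invert_transform(intercept, transform),
         ci_low = ci[[1L]], ci_high = ci[[2L]],
         variance_components = comps, fixed_effects = fixed,
         var_fixed = var_fixed,
         n_obs = nrow(d), n_chambers = nlevels(d$chamber),
         n_dates = nlevels(d$date),
         singular = singular, transform = transform, fit = fit),
    class = "mixed_model_result")
  r2 <- tryCatch(nakagawa_r2(res), error = function(e) c(NA_real_, NA_real_))
  res$r2_marginal <- r2[[1L]]
  res$r2_conditional <- r2[[2L]]
  res
}

#' @export
print.mixed_model_result <- function(x, ...) {
  cat(sprintf(
    paste0("<mixed_model_result> geometric mean %.4g [%.4g, %.4g] ",
           "(%s; n = %d, %d chambers, %d dates%s)\n"),
    x$geometric_mean, x$ci_low, x$ci_high, x$transform$method,
    x$n_obs, x$n_chambers, x$n_dates,
    if (isTRUE(x$singular)) ", singular fit" else ""))
  cat("  variance components:",
      paste(sprintf("%s = %.4g", names(x$variance_components),
                    x$variance_components), collapse = ", "), "\n")
  invisible(x)
}

#' Environmental driver model for log-scale fluxes
#'
#' Fits, by REML, `y ~ soil_temperature + wfps + (1 | chamber)` to the
#' transformed fluxes, reporting each fixed effect both on the log scale
#' and as the percent change in flux per unit covariate,
#' `(exp(beta) - 1) * 100`. A covariate with no variation is dropped and
#' marked non-estimable. A single-chamber panel falls back to ordinary
#' least squares (the random intercept is then unidentifiable).
#'
#' @inheritParams fit_geometric_mean_model
#' @param covariates Character vector of covariate columns; default
#'   `c("soil_temperature", "wfps")`.
#' @return A `mixed_model_result`; `fixed_effects` has one row per term
#'   with `estimate`, `se`, `percent_change`, `ci_low_pct`, `ci_high_pct`
#'   and `estimable`.
#' @export
fit_driver_model <- function(panel,
                             transform = transform_spec("log_positive"),
                             covariates = c("soil_temperature", "wfps")) {
  check_flux_panel(panel)
  missing <- setdiff(covariates, names(panel))
  if (length(missing)) {
    stop("missing covariate columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  d <- data.frame(y = apply_transform(panel$flux, transform),
                  chamber = factor(panel$chamber_id))
  for (cv in covariates) {
    if (any(!is.finite(panel[[cv]]))) {
      stop("covariate `", cv, "` has non-finite values", call. = FALSE)
    }
    d[[cv]] <- panel[[cv]]
  }
  estimable <- vapply(covariates, function(cv) stats::var(d[[cv]]) > 0,
                      logical(1))
  dropped <- covariates[!estimable]
  kept <- covariates[estimable]
  if (length(dropped)) {
    warning("constant covariate(s) dropped as non-estimable: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  }
  rhs <- if (length(kept)) paste(kept, collapse = " + ") else "1"
  single_chamber <- nlevels(d$chamber) < 2L
  if (single_chamber) {
    fit <- stats::lm(stats::as.formula(paste("y ~", rhs)), data = d)
    sm <- summary(fit)$coefficients
    comps <- c(chamber = 0, residual = stats::sigma(fit)^2)
    singular <- FALSE
  } else {
    form <- stats::as.formula(paste("y ~", rhs, "+ (1 | chamber)"))
    fit <- lme4::lmer(form, data = d, REML = TRUE,
                      control = lme4::lmerControl(calc.derivs = FALSE))
    sm <- summary(fit)$coefficients
    comps <- varcomp_table(fit)
    singular <- lme4::isSingular(fit)
  }
  fe <- data.frame(term = rownames(sm), estimate = sm[, "Estimate"],
                   se = sm[, "Std. Error"], row.names = NULL,
                   stringsAsFactors = FALSE)
  fe$percent_change <- ifelse(fe$term == "(Intercept)", NA_real_,
                              percent_change(fe$estimate))
  fe$ci_low_pct <- ifelse(fe$term == "(Intercept)", NA_real_,
                          percent_change(fe$estimate - 1.96 * fe$se))
  fe$ci_high_pct <- ifelse(fe$term == "(Intercept)", NA_real_,
                           percent_change(fe$estimate + 1.96 * fe$se))
  fe$estimable <- TRUE
  if (length(dropped)) {
    fe <- rbind(fe, data.frame(term = dropped, estimate = NA_real_,
                               se = NA_real_, percent_change = NA_real_,
                               ci_low_pct = NA_real_, ci_high_pct = NA_real_,
                               estimable = FALSE))
  }
  # Fixed-effect predictor variance over the data (population-level).
  var_fixed <- if (length(kept)) {
    X <- as.matrix(d[, kept, drop = FALSE])
    beta <- fe$estimate[match(kept, fe$term)]
    stats::var(as.numeric(X %*% beta)) * (nrow(d) - 1) / nrow(d)
  } else 0
  finish_mixed_result(
    intercept = sm["(Intercept)", "Estimate"],
    intercept_se = sm["(Intercept)", "Std. Error"],
    comps = comps, fixed = fe, var_fixed = var_fixed,
    d = d, transform = transform, singular = singular, fit = fit)
}

#' Percent change implied by a log-scale coefficient
#'
#' `(exp(effect) - 1) * 100`: the percent change in the (back-transformed)
#' response per unit increase of the covariate.
#'
#' @param effect Log-scale coefficient (vectorised).
#' @return Percent change.
#' @examples
#' percent_change(log(2))  # 100
#' @export
percent_change <- function(effect) {
  stopifnot(is.numeric(effect), all(is.finite(effect)))
  (exp(effect) - 1) * 100
}

#' Marginal and conditional R2 for a mixed model
#'
#' Variance-partition R2 following Nakagawa & Schielzeth: the marginal R2
#' is the share of total variance explained by the fixed effects,
#' `var_f / (var_f + sum(var_random) + var_resid)`, and the conditional R2
#' adds the random-effect variance to the numerator. `var_f` is the
#' variance of the fixed-effect linear predictor over the data.
#'
#' @param result A `mixed_model_result`.
#' @return Named numeric vector `c(r2_marginal, r2_conditional)`.
#' @export
nakagawa_r2 <- function(result) {
  stopifnot(inherits(result, "mixed_model_result"))
  comps <- result$variance_components
  var_resid <- comps[["residual"]]
  var_rand <- sum(comps[setdiff(names(comps), "residual")])
  denom <- result$var_fixed + var_rand + var_resid
  if (denom <= 0) stop("total variance is zero; R2 undefined", call. = FALSE)
  c(r2_marginal = result$var_fixed / denom,
    r2_conditional = (result$var_fixed + var_rand) / denom)
}

#' Summarize a flux panel by forest type
#'
#' Applies [fit_geometric_mean_model()] to each forest type of a panel
#' (splitting the swamp type by the `inundated` flag when present) and
#' collects the geometric means and 95% CIs into a table.
#'
#' @param panel Flux panel.
#' @param transforms Named list of [transform_spec()] keyed by the group
#'   labels; a single spec is recycled. Groups not listed default to
#'   `log_positive` when all fluxes are positive and `negate_log` when all
#'   are negative, failing otherwise with instructions.
#' @return Data frame with `forest_type`, `point`, `ci_low`, `ci_high`,
#'   `transform`, `n_obs`, `singular`.
#' @export
summarize_by_forest_type <- function(panel, transforms = NULL) {
  check_flux_panel(panel)
  grp <- as.character(panel$forest_type)
  if (!is.null(panel$inundated)) {
    grp <- ifelse(grp == "swamp" & panel$inundated, "swamp_inundated",
                  ifelse(grp == "swamp", "swamp_non_inundated", grp))
  }
  out <- lapply(unique(grp), function(g) {
    sub <- panel[grp == g, , drop = FALSE]
    sub$forest_type <- g
    tr <- if (inherits(transforms, "transform_spec")) transforms
      else transforms[[g]]
    if (is.null(tr)) {
      tr <- if (all(sub$flux > 0)) transform_spec("log_positive")
        else if (all(sub$flux < 0)) transform_spec("negate_log")
        else stop("group `", g, "` has mixed-sign fluxes; supply a ",
                  "shifted_log transform_spec for it", call. = FALSE)
    }
    m <- fit_geometric_mean_model(sub, tr)
    data.frame(forest_type = g, point = m$geometric_mean,
               ci_low = m$ci_low, ci_high = m$ci_high,
               transform = tr$method, n_obs = m$n_obs,
               singular = m$singular, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
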
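#' Forest-type coverage weights for basin upscaling
#'
#' Areal share of each forest type in the basin's humid forest cover,
#' defaulting to 90.6% lowland, 6.8% swamp and 2.6% montane, with the
#' swamp area split between inundated and non-inundated states by
#' `inundated_fraction`.
#'
#' @param lowland,swamp,montane Area fractions; must be non-negative and
#'   sum to 1 (within 1e-9).
#' @param inundated_fraction Fraction of the swamp area that is inundated,
#'   in \[0, 1\]; default 0.5.
#' @return A list of class `coverage_weights`.
#' @export
coverage_weights <- function(lowland = 0.906, swamp = 0.068,
                             montane = 0.026, inundated_fraction = 0.5) {
  w <- c(lowland = lowland, swamp = swamp, montane = montane)
  if (any(w < 0)) stop("coverage weights must be >= 0", call. = FALSE)
  if (abs(sum(w) - 1) > 1e-9) {
    stop("coverage weights must sum to 1 (got ", sum(w), ")", call. = FALSE)
  }
  if (inundated_fraction < 0 || inundated_fraction > 1) {
    stop("`inundated_fraction` must be in [0, 1]", call. = FALSE)
  }
  structure(list(lowland = lowland, swamp = swamp, montane = montane,
                 inundated_fraction = inundated_fraction),
            class = "coverage_weights")
}

#' Per-forest-type flux estimate with confidence bounds
#'
#' @param forest_type Label, e.g. `"lowland"`.
#' @param point Point estimate (kg element ha^-1 yr^-1 in reporting use).
#' @param ci_low,ci_high 95% confidence bounds; must bracket `point`.
#' @return A list of class `type_estimate`.
#' @export
type_estimate <- function(forest_type, point, ci_low = point,
                          ci_high = point) {
  if (ci_low > point || point > ci_high) {
    stop("confidence bounds must satisfy ci_low <= point <= ci_high",
         call. = FALSE)
  }
  structure(list(forest_type = forest_type, point = point,
                 ci_low = ci_low, ci_high = ci_high),
            class = "type_estimate")
}

#' @export
print.type_estimate <- function(x, ...) {
  cat(sprintf("<type_estimate> %s: %.4g [%.4g, %.4g]\n",
              x$forest_type, x$point, x$ci_low, x$ci_high))
  invisible(x)
}

#' Composite swamp estimate from its inundated and non-inundated states
#'
#' The swamp forest alternates between inundated and dry regimes with very
#' different fluxes; the composite weights the two by the inundated area
#' fraction, bound-wise for the confidence limits:
#' `f * inundated + (1 - f) * non_inundated`.
#'
#' @param inundated,non_inundated [type_estimate()]s for the two states.
#' @param f Inundated area fraction, in \[0, 1\].
#' @return A `type_estimate` labelled `"swamp"`.
#' @examples
#' swamp_composite(type_estimate("swamp_inundated", 341, 147, 798),
#'                 type_estimate("swamp_non_inundated", 2.68, -3.03, 12.09),
#'                 f = 0.5)
#' @export
swamp_composite <- function(inundated, non_inundated, f = 0.5) {
  stopifnot(inherits(inundated, "type_estimate"),
            inherits(non_inundated, "type_estimate"))
  if (f < 0 || f > 1) stop("`f` must be in [0, 1]", call. = FALSE)
  mix <- function(a, b) f * a + (1 - f) * b
  type_estimate("swamp",
                point = mix(inundated$point, non_inundated$point),
                ci_low = mix(inundated$ci_low, non_inundated$ci_low),
                ci_high = mix(inundated$ci_high, non_inundated$ci_high))
}

#' Coverage-weighted basin mean flux
#'
#' Combines the lowland, montane and (composite) swamp estimates into a
#' basin-wide average weighted by forest-type coverage. Confidence bounds
#' are combined bound-wise with the same weights by default; a quadrature
#' option propagates half-widths as independent errors instead.
#'
#' @param estimates List of [type_estimate()]s covering `lowland`,
#'   `montane` and `swamp` (order-free; matched on `forest_type`).
#' @param weights A [coverage_weights()].
#' @param ci_method `"boundwise"` (default) or `"quadrature"`.
#' @return A `type_estimate` labelled `"basin"`.
#' @examples
#' ests <- list(
#'   type_estimate("lowland", -3.52, -4.29, -2.68),
#'   type_estimate("montane", -4.28, -4.70, -3.80),
#'   swamp_composite(type_estimate("swamp_inundated", 341, 147, 798),
#'                   type_estimate("swamp_non_inundated", 2.68, -3.03, 12.09)))
#' basin_weighted_mean(ests)  # 8.38 [0.89, 25.02]
#' @export
basin_weighted_mean <- function(estimates, weights = coverage_weights(),
                                ci_method = c("boundwise", "quadrature")) {
  ci_method <- match.arg(ci_method)
  stopifnot(inherits(weights, "coverage_weights"))
  types <- vapply(estimates, function(e) e$forest_type, character(1))
  needed <- c("lowland", "montane", "swamp")
  missing <- setdiff(needed, types)
  if (length(missing)) {
    stop("missing forest type(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  e <- estimates[match(needed, types)]
  w <- c(weights$lowland, weights$montane, weights$swamp)
  point <- sum(w * vapply(e, `[[`, numeric(1), "point"))
  if (ci_method == "boundwise") {
    lo <- sum(w * vapply(e, `[[`, numeric(1), "ci_low"))
    hi <- sum(w * vapply(e, `[[`, numeric(1), "ci_high"))
  } else {
    half_lo <- vapply(e, function(x) x$point - x$ci_low, numeric(1))
    half_hi <- vapply(e, function(x) x$ci_high - x$point, numeric(1))
    lo <- point - sqrt(sum((w * half_lo)^2))
    hi <- point + sqrt(sum((w * half_hi)^2))
  }
  type_estimate("basin", point, lo, hi)
}

#' Relative difference between two fluxes
#'
#' `(value - reference) / |reference| * 100`, the signed percent deviation
#' of an estimate from a reference value.
#'
#' @param value,reference Fluxes in the same units; `reference` non-zero.
#' @return Percent difference (unrounded; see [round_report()]).
#' @examples
#' relative_difference(1.55, 1.17)  # ~ +32 %
#' @export
relative_difference <- function(value, reference) {
  stopifnot(is.numeric(value), is.numeric(reference))
  if (any(reference == 0)) stop("`reference` must be non-zero", call. = FALSE)
  (value - reference) / abs(reference) * 100
}

#' Round half away from zero for report output
#'
#' Published flux tables round half away from zero (2.675 -> 2.68), unlike
#' R's banker's rounding; use this for report-facing values.
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 2).
#' @return Rounded values.
#' @export
round_report <- function(x, digits = 2) {
  p <- 10^digits
  # epsilon guards against binary representation of exact halves (2.675)
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}
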
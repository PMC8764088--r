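#' Chamber isotope pair (closure start and end)
#'
#' The inputs of the two-source mixing model: N2O mole fraction and delta
#' values sampled immediately after chamber closure and shortly before
#' opening. Per-position d15N (alpha: central N; beta: terminal N) is
#' optional and enables flux site-preference estimates.
#'
#' @param chamber_id Identifier.
#' @param c_start,c_end N2O mole fraction at closure start/end, nmol mol^-1.
#' @param d15n_start,d15n_end Bulk d15N, permil vs. air-N2.
#' @param d18o_start,d18o_end d18O, permil vs. VSMOW.
#' @param d15n_alpha_start,d15n_alpha_end,d15n_beta_start,d15n_beta_end
#'   Optional per-position d15N, permil.
#' @return A list of class `isotope_pair`.
#' @export
isotope_pair <- function(chamber_id, c_start, c_end,
                         d15n_start = NA_real_, d15n_end = NA_real_,
                         d18o_start = NA_real_, d18o_end = NA_real_,
                         d15n_alpha_start = NA_real_, d15n_alpha_end = NA_real_,
                         d15n_beta_start = NA_real_, d15n_beta_end = NA_real_) {
  if (c_start <= 0 || c_end <= 0) {
    stop("mole fractions must be > 0", call. = FALSE)
  }
  structure(
    list(chamber_id = chamber_id, c_start = c_start, c_end = c_end,
         d15n_start = d15n_start, d15n_end = d15n_end,
         d18o_start = d18o_start, d18o_end = d18o_end,
         d15n_alpha_start = d15n_alpha_start, d15n_alpha_end = d15n_alpha_end,
         d15n_beta_start = d15n_beta_start, d15n_beta_end = d15n_beta_end),
    class = "isotope_pair"
  )
}

#' Two-source (Keeling-type) mixing model for the flux isotopic signature
#'
#' The chamber headspace at the end of a closure is a mixture of the
#' background air present at the start and the N2O emitted by the soil.
#' Mass balance then gives the source signature for each delta:
#' `delta_flux = (c_end * delta_end - c_start * delta_start) / (c_end - c_start)`.
#' The inversion is only reliable when enough N2O accumulated; pairs with
#' a concentration increase below `min_delta` (default 31 ppb) are flagged
#' invalid but retained, so discard counts remain auditable.
#'
#' @param pair An [isotope_pair()].
#' @param min_delta Minimum concentration increase (ppb) for a valid
#'   signature; the boundary is inclusive on the keep side
#'   (`delta_n2o >= min_delta` is valid).
#' @return A list of class `source_signature` with `delta_n2o`, `d15n_flux`,
#'   `d18o_flux`, `sp_flux` (site preference of the flux, when per-position
#'   data are present), `valid` and `reason`.
#' @examples
#' p <- isotope_pair("c1", 330, 430, d15n_start = 6.7, d15n_end = 0.4907)
#' two_source_mixing(p)$d15n_flux  # ~ -20 permil
#' @export
two_source_mixing <- function(pair, min_delta = 31) {
  stopifnot(inherits(pair, "isotope_pair"))
  dc <- pair$c_end - pair$c_start
  mix <- function(d_start, d_end) {
    if (is.na(d_start) || is.na(d_end) || dc == 0) return(NA_real_)
    (pair$c_end * d_end - pair$c_start * d_start) / dc
  }
  if (dc == 0) {
    return(structure(
      list(chamber_id = pair$chamber_id, delta_n2o = 0,
           d15n_flux = NA_real_, d18o_flux = NA_real_, sp_flux = NA_real_,
           valid = FALSE, reason = "no concentration change"),
      class = "source_signature"))
  }
  d15n <- mix(pair$d15n_start, pair$d15n_end)
  d18o <- mix(pair$d18o_start, pair$d18o_end)
  d15a <- mix(pair$d15n_alpha_start, pair$d15n_alpha_end)
  d15b <- mix(pair$d15n_beta_start, pair$d15n_beta_end)
  sp <- if (is.na(d15a) || is.na(d15b)) NA_real_ else site_preference(d15a, d15b)
  valid <- dc >= min_delta
  structure(
    list(chamber_id = pair$chamber_id, delta_n2o = dc,
         d15n_flux = if (valid) d15n else NA_real_,
         d18o_flux = if (valid) d18o else NA_real_,
         sp_flux = if (valid) sp else NA_real_,
         valid = valid,
         reason = if (valid) NA_character_ else
           sprintf("delta N2O %.3g ppb < %g ppb", dc, min_delta)),
    class = "source_signature"
  )
}

#' @export
print.source_signature <- function(x, ...) {
  cat(sprintf(
    "<source_signature> chamber %s: dN2O = %.3g ppb, d15N = %.3g, d18O = %.3g, SP = %.3g (%s)\n",
    x$chamber_id, x$delta_n2o, x$d15n_flux, x$d18o_flux, x$sp_flux,
    if (x$valid) "valid" else x$reason))
  invisible(x)
}

#' Apply the mixing model to a table of isotope pairs
#'
#' @param pairs Data frame with the [isotope_pair()] fields as columns.
#' @inheritParams two_source_mixing
#' @return Data frame of source signatures, one row per pair, invalid rows
#'   retained with `valid = FALSE` and a `reason`.
#' @export
two_source_mixing_table <- function(pairs, min_delta = 31) {
  opt <- c("d15n_start", "d15n_end", "d18o_start", "d18o_end",
           "d15n_alpha_start", "d15n_alpha_end",
           "d15n_beta_start", "d15n_beta_end")
  for (col in opt) if (is.null(pairs[[col]])) pairs[[col]] <- NA_real_
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    p <- do.call(isotope_pair, as.list(
      pairs[i, c("chamber_id", "c_start", "c_end", opt)]))
    s <- two_source_mixing(p, min_delta)
    data.frame(chamber_id = s$chamber_id, delta_n2o = s$delta_n2o,
               d15n_flux = s$d15n_flux, d18o_flux = s$d18o_flux,
               sp_flux = s$sp_flux, valid = s$valid, reason = s$reason,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Site preference of N2O
#'
#' Difference between the d15N of the central (alpha) and terminal (beta)
#' nitrogen position of the linear N2O molecule; diagnostic of the microbial
#' production pathway (low SP: denitrification; high SP: nitrification /
#' fungal denitrification).
#'
#' @param d15n_alpha,d15n_beta Per-position d15N, permil.
#' @return Site preference in permil (vectorised).
#' @examples
#' site_preference(10, 2)  # 8
#' @export
site_preference <- function(d15n_alpha, d15n_beta) {
  stopifnot(is.numeric(d15n_alpha), is.numeric(d15n_beta))
  d15n_alpha - d15n_beta
}

# Equilibrium fractionation factors alpha_eq = R_headspace / R_dissolved for
# N2O between water and headspace.
ALPHA_EQ <- c(`15N` = 0.99925, `18O` = 0.99894)

#' Correct a headspace delta to the dissolved phase
#'
#' Vial headspace measurements of dissolved N2O are isotopically offset from
#' the water phase by equilibrium fractionation,
#' `alpha_eq = R_headspace / R_dissolved` (0.99925 for 15N, 0.99894 for
#' 18O). This inverts that offset:
#' `delta_dissolved = ((delta_headspace/1000 + 1)/alpha_eq - 1) * 1000`.
#'
#' @param delta_headspace Measured headspace delta, permil; must exceed
#'   -1000 (a physical ratio).
#' @param isotope `"15N"` or `"18O"`.
#' @return Dissolved-phase delta, permil.
#' @examples
#' dissolved_delta_correction(0, "15N")  # 0.7506
#' @export
dissolved_delta_correction <- function(delta_headspace,
                                       isotope = c("15N", "18O")) {
  isotope <- match.arg(isotope)
  stopifnot(is.numeric(delta_headspace))
  if (any(delta_headspace <= -1000)) {
    stop("delta values must be > -1000 permil", call. = FALSE)
  }
  a <- ALPHA_EQ[[isotope]]
  ((delta_headspace / 1000 + 1) / a - 1) * 1000
}

#' Empirical N2O reduction vector in (d15N, d18O) space
#'
#' During reduction of N2O to N2 by denitrifiers, the residual N2O becomes
#' enriched in both 15N and 18O along a characteristic direction with slope
#' ~2.4 (d18O per d15N). The vector is anchored at a reference point,
#' conventionally tropospheric N2O.
#'
#' @param slope d18O-per-d15N ratio; default 2.4.
#' @param anchor Numeric length-2 `(d15N0, d18O0)` starting point in permil;
#'   default `c(6.7, 44.6)`, a tropospheric N2O reference composition.
#' @return A list of class `reduction_vector`.
#' @export
reduction_vector <- function(slope = 2.4, anchor = c(6.7, 44.6)) {
  stopifnot(is.numeric(slope), length(slope) == 1L,
            is.numeric(anchor), length(anchor) == 2L)
  if (slope <= 0) stop("`slope` must be > 0", call. = FALSE)
  structure(list(slope = slope, anchor = as.numeric(anchor)),
            class = "reduction_vector")
}

#' Project an isotope observation onto the reduction vector
#'
#' Orthogonally decomposes `point - anchor` onto the unit direction
#' `(1, slope)/sqrt(1 + slope^2)` and its normal. `progress` measures how
#' far along the reduction trajectory the observation lies (permil, in the
#' combined delta space); `residual` is the signed perpendicular distance,
#' positive above the line.
#'
#' @param point Numeric length-2 `(d15N, d18O)` in permil.
#' @param vector A [reduction_vector()].
#' @return List with `progress` and `residual`.
#' @examples
#' reduction_projection(c(7.7, 47.0), reduction_vector())
#' @export
reduction_projection <- function(point, vector = reduction_vector()) {
  stopifnot(inherits(vector, "reduction_vector"),
            is.numeric(point), length(point) == 2L)
  d <- as.numeric(point) - vector$anchor
  u <- c(1, vector$slope) / sqrt(1 + vector$slope^2)
  n <- c(-u[2], u[1])                      # left-hand normal: positive above
  list(progress = sum(d * u), residual = sum(d * n))
}

#' Literature end-member boxes for N2O production pathways
#'
#' Named rectangles in (d15N, d18O) space within which N2O produced by
#' nitrification or denitrification is expected to fall. The shipped
#' defaults are indicative literature-style ranges, not normative values;
#' supply study-specific boxes for real classifications.
#'
#' @param boxes Named list; each element is `c(d15n_min, d15n_max,
#'   d18o_min, d18o_max)` in permil.
#' @return A list of class `endmember_boxes`.
#' @export
endmember_boxes <- function(boxes = list(
  nitrification = c(-65, -45, 15, 40),
  denitrification = c(-45, -5, 5, 35))) {
  if (!length(boxes)) stop("box set must be non-empty", call. = FALSE)
  for (nm in names(boxes)) {
    b <- boxes[[nm]]
    if (length(b) != 4L || b[1] >= b[2] || b[3] >= b[4]) {
      stop("box `", nm, "` must be c(d15n_min, d15n_max, d18o_min, d18o_max) ",
           "with min < max on both axes", call. = FALSE)
    }
  }
  structure(list(boxes = boxes), class = "endmember_boxes")
}

#' Classify an isotope observation against the end-member boxes
#'
#' @param point Numeric length-2 `(d15N, d18O)` in permil.
#' @param boxes An [endmember_boxes()].
#' @return One of the box names, `"outside"`, or `"ambiguous"` when the
#'   point lies in more than one box.
#' @export
classify_endmember <- function(point, boxes = endmember_boxes()) {
  stopifnot(inherits(boxes, "endmember_boxes"),
            is.numeric(point), length(point) == 2L)
  inside <- vapply(boxes$boxes, function(b) {
    point[1] >= b[1] && point[1] <= b[2] &&
      point[2] >= b[3] && point[2] <= b[4]
  }, logical(1))
  hits <- names(boxes$boxes)[inside]
  if (length(hits) == 0L) "outside"
  else if (length(hits) > 1L) "ambiguous"
  else hits
}
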
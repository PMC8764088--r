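# Independent oracles kept deliberately naive: closed-form normal
# equations, forward mass balances and hand arithmetic, never the package's
# own code paths.

# OLS slope and R^2 from the normal equations.
ols_oracle <- function(x, y) {
  n <- length(x)
  sxx <- sum(x^2) - sum(x)^2 / n
  sxy <- sum(x * y) - sum(x) * sum(y) / n
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  ss_res <- sum((y - intercept - slope * x)^2)
  ss_tot <- sum((y - mean(y))^2)
  list(slope = slope, r_squared = 1 - ss_res / ss_tot)
}

# Forward two-pool isotope mixing: add `a` ppb of source at delta `ds` to a
# background (c0, d0) pool.
forward_mix <- function(c0, d0, a, ds) {
  list(c_end = c0 + a, d_end = (c0 * d0 + a * ds) / (c0 + a))
}

# Headspace mole fraction (ppb) of an N2-flushed vial equilibrated with
# water holding `conc_molar` mol L^-1, from the two-compartment balance
# n_tot = x P (V_hs/(R T) + kH V_w).
vial_headspace_oracle <- function(conc_molar, v_w_ml, v_hs_ml, temp_k, kh,
                                  pressure = 1) {
  r <- 0.08206
  n_tot <- conc_molar * v_w_ml / 1000
  x <- n_tot / (pressure * ((v_hs_ml / 1000) / (r * temp_k) +
                              kh * v_w_ml / 1000))
  x * 1e9
}

# Minimal hand-built flux panel for the variability summaries.
make_panel <- function(flux, chamber_id, date, site = "s1",
                       forest_type = "lowland", week = NULL) {
  p <- data.frame(site = site, forest_type = forest_type,
                  chamber_id = chamber_id, date = as.Date(date),
                  flux = flux, stringsAsFactors = FALSE)
  if (!is.null(week)) p$week <- week
  p
}
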
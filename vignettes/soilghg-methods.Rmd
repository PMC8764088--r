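---
title: "Methods behind soilghg: from chamber headspace to basin budget"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind soilghg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soilghg)
```

This vignette explains the models and procedures the package implements,
the assumptions behind them, and the numerical and design choices made
where the field's conventions leave room.

## 1. Chamber flux estimation

A non-steady-state static chamber (the common design: a cylinder with
d = h = 0.30 m, giving V = 21.2 L over S = 0.0707 m²) is closed for one
hour and its headspace sampled at t = 0, 20, 40, 60 min. The mole fraction
trend is fitted by ordinary least squares on minutes and converted once to
per-second units; the flux is

$$F = \frac{\Delta n}{\Delta t} \cdot \frac{1}{S}, \qquad n = \frac{PV}{RT},$$

with R = 0.08206 L atm K⁻¹ mol⁻¹ and the micrometeorological sign
convention (negative = uptake). Assumptions: the headspace is well mixed
(field protocols pump the syringe before sampling), accumulation is linear
over the closure (no saturation feedback), and mole fractions are dry-air
values (no water-vapour dilution correction is applied).

Choices worth stating explicitly:

* **Temperature entering n = PV/RT.** The thermocouple logs a headspace
  temperature at every sampling point but the flux formula needs one value.
  The default is the arithmetic mean over the closure — the inventory the
  slope acts on is the average-state inventory — with a `"first"` option
  for protocols that fix the inventory at closure.
* **R² of a constant series.** A zero-variance series has an undefined
  coefficient of determination; the package defines it as 0 with
  `qc_pass = FALSE`. This matters because the quality flag must *keep* such
  records: low R² accompanies near-zero fluxes, and discarding them would
  bias the record towards high fluxes. `retained` is therefore always
  `TRUE`; QC is a flag, not a filter.
* **QC threshold.** R² > 0.95 as a strict inequality, configurable.
* **Single OLS slope, not per-interval increments.** With four points the
  OLS slope is the minimum-variance linear estimate; per-interval Δn
  averaging gives the same expectation with more variance.
* **Floating chambers** (V = 17 L, used over standing water) rarely report
  a footprint; `area` defaults to the static π·0.15² m² and should be set
  when known.

Nonlinear (HMR-style) flux models, leakage and vent corrections are out of
scope.

## 2. Units

Instantaneous fluxes (nmol m⁻² s⁻¹) convert to annual element-mass fluxes
(kg CH₄-C or N₂O-N ha⁻¹ yr⁻¹) by
`flux × 1e-9 × element_mass × seconds_per_year × 1e4 / 1e3`, with IUPAC
2021 masses (C 12.011; N₂O-N 2 × 14.007 = 28.014 g mol⁻¹) and a 365.25-day
year (3.15576 × 10⁷ s; the difference to a 365-day year is < 0.07 %, below
any printed rounding). One nmol m⁻² s⁻¹ is 3.7904 kg CH₄-C or 8.8405 kg
N₂O-N ha⁻¹ yr⁻¹.

## 3. Dissolved gases by headspace equilibration

A 12 mL vial holds 6 mL of bubble-free stream water under an N₂-flushed
headspace; after equilibration the headspace mole fraction $x$ is measured.
With Henry solubility $k_H(T) = k_{H,298}\exp\!\big(b(1/T - 1/298.15)\big)$
the two compartments hold

$$n_{hs} = \frac{xPV_{hs}}{RT}, \qquad n_{aq} = k_H(T)\,xP\,V_w,$$

and the original in-stream concentration is
$(n_{hs} + n_{aq} - n_{init})/V_w$. Defaults (overrideable, in the style of
the standard solubility compilations): CH₄ $k_{H,298}$ = 1.4 × 10⁻³
mol L⁻¹ atm⁻¹, b = 1750 K; N₂O 2.4 × 10⁻², b = 2700 K. Atmospheric mixing
ratios default to 1870 ppb CH₄ and 332 ppb N₂O (late-2010s atmosphere).
Freshwater is assumed (zero salinity) and ZnCl₂ preservation is taken as
perfect. Temperatures outside 263–323 K warn about van't Hoff
extrapolation.

**Mass basis of the N₂O equilibrium reference.** On an N-mass basis the
N₂O atmospheric equilibrium at 25 °C is ≈ 0.22 µg N L⁻¹, while the commonly
quoted reference 0.36 µg L⁻¹ is only consistent with a full-molecule
(44 g mol⁻¹) basis. `equilibrium_concentration()` supports both
(`mass_basis = "element"` / `"molecule"`) and defaults to the element
basis used for every other concentration in the package; the discrepancy
is surfaced rather than silently matched.

## 4. N₂O isotope analytics

Over a closure the headspace is a two-pool mixture of background air and
soil-emitted N₂O, so each delta's source value follows from mass balance:

$$\delta_{flux} = \frac{c_{end}\,\delta_{end} - c_{start}\,\delta_{start}}
                       {c_{end} - c_{start}}.$$

The inversion amplifies measurement error when little N₂O accumulates;
pairs with ΔN₂O < 31 ppb are marked invalid — the boundary is inclusive on
the keep side (Δ = 31 is valid) since the discard rule is stated as
"below 31". Invalid pairs are retained with a reason string so discard
counts stay auditable. Site preference is δ¹⁵Nα − δ¹⁵Nβ; when per-position
deltas are supplied the flux SP comes from applying the mixing model per
position, which is exact for mass-balance mixing (the per-position route
is one of two defensible conventions; it is the one implemented, and it is
flagged as such here).

Dissolved-phase deltas measured in a vial headspace are corrected through
the equilibrium fractionation factors α_eq = R_headspace/R_dissolved
(0.99925 for ¹⁵N, 0.99894 for ¹⁸O):
δ_dissolved = ((δ_hs/1000 + 1)/α_eq − 1)·1000.

The reduction-vector map decomposes (δ¹⁵N, δ¹⁸O) observations, relative to
a tropospheric anchor (default (6.7, 44.6) ‰), onto the empirical
direction of slope 2.4 along which residual N₂O is enriched during
reduction to N₂; `progress` is the distance along that direction and
`residual` the signed perpendicular offset. End-member rectangles for
nitrification vs. denitrification ship as indicative literature-style
defaults only — published figures rarely print coordinates — and should be
replaced by study-specific ranges; classification returns `ambiguous` on
overlap and `outside` on no hit.

## 5. Mixed-model flux statistics

Fluxes are approximately lognormal, so per-forest-type central tendency is
estimated as the exponentiated intercept of a REML linear mixed model on
transformed fluxes with chamber-nested-in-plot and sampling-date random
intercepts (`lme4`):

$$y_{ijk} = \mu + b_{plot(i)} + b_{chamber(i)} + b_{date(j)} +
            \varepsilon_{ijk}.$$

The back-transformed intercept is the geometric mean (the median under
lognormality); the 95 % interval is Wald on the transformed scale,
μ ± 1.96·SE, back-transformed — the simplest construction consistent with
reporting "geometric mean [95 % CI]". Panels with a single plot collapse
the plot level into the chamber term to avoid a structurally singular fit.

**Negative fluxes.** The log transform is undefined for CH₄ uptake, and no
single convention is standard, so the transform is a mandatory, recorded
choice: `log_positive` (errors on any non-positive flux, naming the
offending records), `negate_log` (all-negative panels; the back-transform
restores the sign, so an uptake panel yields a negative geometric mean
with ordered CIs), and `shifted_log` with a user-set offset for mixed-sign
panels. `summarize_by_forest_type()` defaults per group by sign and
refuses to guess for mixed-sign groups.

Driver models use `y ~ temperature + wfps + (1 | chamber)`; effects are
reported raw and as percent change per unit, (e^β − 1)·100. Constant
covariates are dropped and flagged non-estimable; single-chamber panels
fall back to OLS, to which the mixed model is then equivalent. WFPS comes
from volumetric water content as 100·vwc/(1 − BD/PD) with particle density
2.65 g cm⁻³. Nakagawa–Schielzeth R² is computed from the variance of the
fixed-effect predictor and the fitted variance components:
R²m = σ²_f / (σ²_f + Σσ²_r + σ²_ε), R²c adds Σσ²_r to the numerator.
Singular fits are reported with their zeroed components and a flag, never
silently dropped. Variance summaries (between-chamber and intra-annual)
are plain dispersions of chamber averages and of weekly site means, weeks
being ISO week numbers pooled across years.

Temporal autocorrelation, interpolation-based gap filling and Bayesian
fits are out of scope.

## 6. Basin upscaling

Per-type estimates combine linearly with coverage weights (defaults 0.906
lowland, 0.068 swamp, 0.026 montane). The swamp type is a composite of its
inundated and non-inundated regimes, f·inundated + (1 − f)·non-inundated
applied to the point and to each CI bound.

* **Inundated fraction f = 0.5.** Published basin-wide summaries do not
  state the swamp split. f = 0.5 is adopted because it is the only value
  that reconciles the published CH₄ *and* N₂O weighted averages
  simultaneously at 2-decimal rounding (two independent checks; the
  sensitivity test in the suite shows any f outside ≈ [0.49, 0.51] breaks
  at least one). It is documented as inferred, not quoted.
* **Bound-wise CI combination.** Confidence bounds are weighted bound-wise
  rather than propagated in quadrature; this reproduces three of the four
  published basin bounds exactly (0.89, 1.19, 2.02) and the fourth to
  within one unit in the last digit (25.02 vs. 25.03 from the printed
  per-type inputs — the residue of upstream rounding of the swamp values),
  which is the empirical argument that it is the convention used. A
  quadrature option exists but is off by default.
* **Rounding.** Report output rounds half away from zero to 2 decimals,
  matching how published tables round; R's default banker's rounding
  differs at exact halves.

Coverage-weight uncertainty and GIS-based mapping are out of scope.

## 7. Synthetic data: what it emulates, and what it does not

Each generator is the exact inverse of its analysis stage at zero noise,
which is what makes round-trip testing meaningful:

* `generate_chamber_series()` inverts the flux formula (linear rise
  `F·S·t/n`, optional exponential flattening with time constant τ for
  saturation behaviour, Gaussian ppb noise). If a strong uptake would
  drive the series below zero from its baseline, the whole series is
  lifted — the flux depends only on the slope, and mole fractions must
  stay physical.
* `generate_flux_panel()` draws
  log|flux| = log|median| + b_plot + b_chamber + b_date + β_t(T − T̄) +
  β_w(W − W̄) + ε with independent Gaussian effects, covariates uniform in
  their ranges, and a sign regime (positive, negative, or mixed via a
  shift). Default log-scale SDs (0.4 chamber, 0.3 date, 0.5 residual) are
  of the magnitude mixed models on weekly-to-fortnightly tropical flux
  panels typically estimate; the default design, 5 chambers × 52 weekly
  dates × 1 plot, mirrors a one-year core-site monitoring campaign with
  five permanently installed chambers.
* `generate_stream_sample()` solves the vial mole balance for the
  headspace mole fraction implied by a known dissolved concentration.
* `generate_isotope_pairs()` forward-mixes a source into a background pool
  and deliberately includes sub-31-ppb additions to exercise the filter.

Every generator draws from a private RNG stream derived from the user seed
plus a per-generator salt, restoring the caller's RNG state, so composed
pipelines are reproducible regardless of call order.

What the generators do **not** emulate — and therefore what passing tests
cannot show about real data: temporal autocorrelation and seasonality
(dates are exchangeable), non-Gaussian heavy tails and episodic emission
events (real swamp records contain sporadic extreme releases), correlated
covariates (temperature and moisture are sampled independently), chamber
relocation and unbalanced sampling, instrument drift, and storage effects
on vials. Field-data summaries such as observed site-preference means,
stream concentration means, or the fraction of closures passing QC depend
on the deposited raw data and are deliberately not asserted anywhere; the
suites verify the estimators those statistics run through instead.

## 8. Numerical choices and problem sizes

REML fits use `lme4` defaults (with derivative checks disabled for speed);
Wald z = 1.96 throughout; degenerate constant panels short-circuit to the
constant with zero components rather than entering a singular optimisation.
The recovery studies run 200 replicates of the 5 × 52 design (the
simulation sizes chosen for the shipped checks; ~1 lmer fit per replicate),
property suites use 100–1000 random cases under fixed seeds, and the
generator law-of-large-numbers checks use 10⁴ draws. Doubles written to
delimited output are serialised at 17 significant digits so write–read
cycles are value-exact.

## 9. Known limitations

* The mixing-model SP route assumes per-position deltas mix linearly in
  concentration, exact for mass balance but sensitive to calibration
  offsets between positions.
* Wald CIs on the log scale undercover slightly for small chamber counts;
  with 5 chambers the dominant variance component is estimated with 4
  effective degrees of freedom. The recovery suite quantifies this
  (coverage ≥ 85 % at the default design).
* `exp(intercept)` estimates the geometric mean, which is the median, not
  the arithmetic mean, of a lognormal flux distribution; annual budgets
  built from it are medians of sustained rates, not time-integrated means.
* The basin upscaling treats per-type point estimates and bounds as fixed
  inputs; it propagates no sampling covariance between types.
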
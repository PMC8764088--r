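# soilghg

Analysis tools for static-chamber soil greenhouse-gas studies in tropical
forest landscapes. The package covers the full chain from raw field
measurements to a basin-scale budget:

1. **Chamber fluxes** — a closed chamber on the soil accumulates (or
   depletes) CH₄ and N₂O in its headspace; the flux follows from the OLS
   slope of concentration against time and the ideal gas law,

   *n* = *PV*/*RT*  and  *F* = (Δ*n*/Δ*t*) / *S*,

   with *R* = 0.08206 L atm K⁻¹ mol⁻¹, reported in nmol m⁻² s⁻¹ under the
   micrometeorological sign convention (negative = uptake). Closures with
   regression R² ≤ 0.95 are flagged, never discarded — low R² mostly means
   a near-zero flux, and dropping those would bias the record upward.
2. **Dissolved gases** — stream-water concentrations from vial headspace
   equilibration via Henry's law (van't Hoff temperature dependence), with
   atmospheric-equilibrium references and saturation ratios.
3. **N₂O isotopes** — source signatures by a two-source (Keeling-type)
   mixing model over a chamber closure, δ¹⁵N site preference, equilibrium
   fractionation correction for dissolved-phase δ values, and projection
   onto the empirical δ¹⁸O/δ¹⁵N ≈ 2.4 reduction vector that diagnoses N₂O
   reduction to N₂ by denitrifiers.
4. **Flux statistics** — fluxes are strongly right-skewed, so per-forest-
   type geometric means come from the exponentiated intercept of a REML
   linear mixed model on log-transformed fluxes with chamber-nested-in-plot
   and sampling-date random intercepts; driver models add soil temperature
   and water-filled pore space as fixed effects, reported as percent change
   per unit, (e^β − 1)·100, with Nakagawa–Schielzeth marginal/conditional
   R².
5. **Upscaling** — forest-type coverage weighting (90.6 % lowland, 6.8 %
   swamp, 2.6 % montane by default) of the per-type estimates into a basin
   mean, with the swamp type composited from its inundated and
   non-inundated states.

Seeded synthetic-data generators emulate every input — linear headspace
accumulation, lognormal flux panels with the mixed-model variance
structure, Henry's-law vial partitioning, forward isotope mixing — so the
whole pipeline is testable end-to-end without field data.

## Worked example

```r
library(soilghg)

geom <- chamber_geometry_from_dimensions(0.30, 0.30)   # V = 21.2 L, S = 0.0707 m^2
s <- headspace_series("KB-3", "N2O", times = c(0, 20, 40, 60),
                      mole_fractions = c(331, 352, 371, 392),  # ppb
                      temperatures = 295.55)                   # K
compute_flux(s, geom)
#> <flux_estimate> chamber KB-3 N2O: 0.2082 nmol m^-2 s^-1 (R^2 = 1.000, QC pass)
nmol_to_annual(0.2082, "N2O")
#> [1] 1.840806   # kg N2O-N ha^-1 yr^-1
```

The headspace rose ~1 ppb min⁻¹, which in a 21.2 L chamber over 0.0707 m²
is 0.21 nmol N₂O m⁻² s⁻¹, i.e. about 1.8 kg N₂O-N ha⁻¹ yr⁻¹ if sustained.

```r
panel <- generate_flux_panel(panel_sim_spec("lowland", true_median = 1.56,
                                            seed = 42))
fit_geometric_mean_model(panel, transform_spec("log_positive"))
#> <mixed_model_result> geometric mean 2.212 [1.258, 3.887]
#>   (log_positive; n = 260, 5 chambers, 52 dates)
#>   variance components: date = 0.07349, chamber = 0.4026, residual = 0.2247
```

One simulated year (5 chambers × 52 dates) at a true median of 1.56: a
single panel's estimate is noisy — with only 5 chambers the between-chamber
variance dominates the intercept's uncertainty — but unbiased across
replicates (see the recovery tests).

```r
ests <- list(
  type_estimate("lowland", -3.52, -4.29, -2.68),
  type_estimate("montane", -4.28, -4.70, -3.80),
  swamp_composite(type_estimate("swamp_inundated", 341, 147, 798),
                  type_estimate("swamp_non_inundated", 2.68, -3.03, 12.09)))
basin_weighted_mean(ests, coverage_weights())
#> <type_estimate> basin: 8.385 [0.886, 25.02]
```

Although 93 % of the area is a CH₄ sink, the swamp source flips the
coverage-weighted basin mean to +8.38 kg CH₄-C ha⁻¹ yr⁻¹: the inundated
swamp flux is two orders of magnitude larger than the lowland uptake.

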
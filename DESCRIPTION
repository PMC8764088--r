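Package: soilghg
Title: Soil Greenhouse-Gas Flux Estimation, Dissolved-Gas and Isotope
    Analytics, and Coverage-Weighted Upscaling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the complete analysis chain of static-chamber soil
    greenhouse-gas studies in tropical forests: chamber headspace flux
    estimation by linear regression and the ideal gas law, dissolved CH4 and
    N2O concentrations from vial headspace equilibration via Henry's law,
    N2O isotope source partitioning with a two-source (Keeling-type) mixing
    model and site preference, log-scale mixed-model geometric mean fluxes
    with confidence intervals and Nakagawa-Schielzeth R2, and area-weighted
    basin upscaling across forest types including an inundated and
    non-inundated swamp composite. Seeded synthetic-data generators emulate
    every input so the whole pipeline is testable without field data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    lme4,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
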
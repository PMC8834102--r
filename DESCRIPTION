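Package: flavomet
Title: Targeted MRM Quantitation, Validation, and Urinary Excretion of
    Flavonoid Metabolites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative pipeline for a targeted LC-MS/MS (multiple
    reaction monitoring) assay of ten flavonoid metabolites of naringin in
    rat urine, with isoquercitrin as internal standard. Provides the panel
    registry with transition mass-consistency checks, weighted (1/x)
    least-squares calibration with back-calculation audits, the full
    bioanalytical validation battery (selectivity, carry-over,
    precision/accuracy, internal-standard normalized matrix factor,
    dilution integrity, stability) with ChP-style acceptance thresholds,
    and molar mass-balance urinary excretion analysis (per-interval nmol,
    cumulative profiles, percent of dose). A seeded synthetic data
    generator emulates linear instrument response with multiplicative
    lognormal noise, per-lot matrix factors, injection carry-over, and
    first-order urinary elimination, so the whole chain is testable
    without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
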
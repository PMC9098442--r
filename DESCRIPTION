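Package: xenoquant
Title: Targeted LC-MS/MS Xenobiotic Quantitation, Method Validation and
    Infant Exposure Assessment
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Data-processing pipeline for multi-class targeted LC-MS/MS
    human-biomonitoring assays. Fits matrix-matched weighted (1/x) linear
    calibrations, estimates limits of detection and quantitation from
    signal-to-noise, and quantifies unknowns with conditional recovery
    correction, solvent-regression blank correction and left-censoring
    rules. Implements guideline-style in-house method validation (recovery,
    intermediate precision, repeatability, linearity, selectivity, matrix
    effects, Horwitz reference tolerances), censoring-aware cohort
    summaries, and a high-exposure breast-milk infant intake and risk
    assessment (hypothetical upper-bound intake, infant-corrected guidance
    values, TDI/ADI ratios and margins of exposure). A synthetic-data
    module emulates calibration series, spiking experiments, contaminated
    blanks and longitudinal exposure cohorts with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
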
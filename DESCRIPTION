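Package: toldmri
Title: Quantitative Oxygenation and Oxygen Consumption Analysis for TOLD MRI
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis pipeline for tissue oxygen level-dependent (TOLD)
    magnetic resonance imaging of gas-challenge experiments. Fits T1 maps
    from variable-repetition-time image series by saturation-recovery
    least squares, converts them to R1 relaxation-rate maps, calibrates
    the T1 relaxivity of dissolved oxygen from R1-versus-pO2 regressions,
    solves a two-compartment (aqueous/lipid) tissue model for volume
    fractions, and converts gas-challenge R1 shifts into quantitative
    tissue oxygen concentration changes in both mM and mmHg-equivalent
    units. TOLD time series are reduced to percent-enhancement curves and
    fitted for the oxygenation rate, plateau amplitude, and oxygen
    consumption rate. A synthetic phantom generator with known ground
    truth stands in for the scanner, and minimal NIfTI-1 input/output with
    JSON sidecars ties the stages into reproducible runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
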
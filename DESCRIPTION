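Package: cellavidity
Title: Cell Avidity Analysis for Centrifuge Force Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of single-cell avidity measurements from centrifuge
    force microscopy (CFM). Converts rotor-speed protocols into per-cell
    centrifugal force, builds normalized cell-detachment curves from
    per-frame fluorescence cell counts, fits stretched-exponential
    population-lifetime models, fits the Poisson bond-number "universal
    curve" linking adhesion frequency to population lifetime, and estimates
    off-rate versus force. Includes a stochastic simulator of Poisson-valent
    load-sharing bond rupture under force ramps and a synthetic dual-channel
    imaging and cell-counting module for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    yaml,
    withr,
    rlang,
    EBImage,
    tiff
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
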
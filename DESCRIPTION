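Package: presynquant
Title: Quantitative Analysis of Presynaptic Fluorescence Imaging and
    Release Kinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying presynaptic function from fluorescence
    reporters: pHluorin exocytosis traces with NH4Cl-plateau normalization
    and signal-to-noise inclusion filters, optical fluctuation analysis of
    single-stimulus Ca2+ transients under a binomial model of voltage-gated
    Ca2+ channel gating with BIC selection among channel-number (N), open
    probability (p) and unitary-signal (q) hypotheses, Hill-equation
    calibration of resting Ca2+ from basal and ionophore-saturated
    indicator signals, FM-dye unloading kinetics by first-order decay fits,
    and paired-pulse ratio computation from field-potential slopes. Seeded
    synthetic-data generators reproduce the statistical structure each
    analysis assumes, supporting parameter-recovery validation end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    minpack.lm,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
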
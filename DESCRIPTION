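Package: oncopop
Title: Simulation of Virtual Oncology Populations from a Hierarchical
    Covariate Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Generates virtual cohorts of adult oncology patients by sampling
    primary variables (tumour type, sex conditional on tumour, biogeographic
    origin, ECOG performance status, Weibull-distributed age) and propagating
    them through a ten-stage cascade of published linear regression equations
    that produce demographic and laboratory variables (height, weight, alpha-1
    acid glycoprotein, albumin, haemoglobin, neutrophil-lymphocyte and
    platelet-lymphocyte ratios, C-reactive protein, lactate dehydrogenase and
    haematocrit). Includes the inverse path (stage-wise ordinary least squares
    refitting with optional stepwise covariate selection), residual-variance
    calibration against marginal targets, goodness-of-fit and normality
    metrics, a library of extrapolation scenarios, and reproducible
    configuration and patient-table input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    graphics,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    nortest,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
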
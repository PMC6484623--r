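Package: lungscreenrisk
Title: Lung Cancer Risk Prediction from LDCT Screening Results
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Risk engine for post-screening lung cancer risk prediction. Combines
    PLCOm2012 6-year risk estimates with the dichotomized Lung-RADS results of
    three annual low-dose CT screens (the PLCO2012results model) to produce
    updated 3-year risks, and solves the ceiling probabilities that drive
    risk-based decisions about omitting or continuing annual screens. Includes
    the full model-development and validation toolchain: fractional-polynomial
    logistic regression with closed-test power selection, discrimination and
    calibration metrics (Brier, AUC, Spiegelhalter, absolute-error percentiles)
    with bias-corrected bootstrap intervals, decision-curve net benefit,
    person-time incidence rates and competing-risks cumulative incidence, and a
    synthetic NLST-like cohort generator for testing and simulation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
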
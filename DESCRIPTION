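Package: ndilute
Title: Critical Nitrogen Dilution Curves and Nitrogen Nutrition Diagnosis
    for Double-Cropped Rice
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constructs and validates critical nitrogen dilution curves for
    rice from leaf dry matter and plant nitrogen concentration measured in
    multi-rate nitrogen field trials. Implements the Justes critical-point
    construction (nitrogen-limited versus non-limited treatment
    classification by ANOVA/Tukey or published significance letters, oblique
    and vertical line intersection per sampling date), power-law dilution
    curve fitting on the log-log or original scale, linearized between-group
    curve comparison, the nitrogen nutrition index (NNI), RMSE/n-RMSE model
    validation with Jamieson stability classes, and the quadratic
    relative-yield response to NNI with its optimum. Ships the published
    treatment-mean table of a Jiangxi double-cropped rice trial as a
    plain-text fixture and a synthetic trial generator with known ground
    truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    rlang,
    stats,
    utils,
    minpack.lm,
    ggplot2,
    withr
Suggests:
    testthat (>= 3.0.0),
    multcomp,
    jsonlite
Config/testthat/edition: 3
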
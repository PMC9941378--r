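Package: bphinge
Title: Hypotension Exposure Metrics and Hinge Threshold Regression for
    Septic ICU Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify hypotension exposure from intensive-care
    blood-pressure time series and to relate it to patient outcomes.
    Implements plausibility filtering, invasive/non-invasive source
    merging and linear interpolation of raw readings to an integer
    one-minute grid; the lowest pressure sustained cumulatively for 120
    minutes and threshold-referenced time-weighted averages for mean,
    systolic, diastolic, and pulse pressure; sepsis cohort construction
    with SOFA scoring, exclusion cascades, and norepinephrine-equivalent
    vasopressor rates; binned moving-average risk curves, penalized
    thin-plate spline logistic regression with generalized
    cross-validation, hinge (change-point) threshold logistic
    regression with profile likelihood and bootstrap intervals,
    categorical odds-ratio tables, subgroup models, and generalized
    variance inflation factors. A synthetic septic-ICU cohort generator
    with known ground truth supports validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    ggplot2,
    jsonlite,
    mgcv,
    stats,
    tools,
    utils,
    yaml
Suggests:
    car,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
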
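Package: panssboost
Title: Boosted Location-Scale Beta Regression for Bounded Symptom-Scale Scores
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Prediction of bounded Likert-sum outcomes, such as five-factor
    totals of the Positive and Negative Syndrome Scale (PANSS), by
    component-wise gradient boosting of a location-scale beta regression.
    Factor totals are rescaled to the open unit interval and modelled with a
    beta distribution whose mean and scale parameters each carry their own
    additive predictor built from equal-degrees-of-freedom linear and P-spline
    base learners. The package provides non-cyclic boosting with early
    stopping, cross-validated selection of the stopping iteration, repeated
    nested cross-validation with optimism estimates, probability integral
    transform calibration for the discretized predictive distributions,
    variable selection frequencies, partial dependence summaries, and a
    synthetic cohort generator with a configurable known truth for end-to-end
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    splines,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
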
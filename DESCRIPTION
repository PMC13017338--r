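Package: vo2compare
Title: Comparison of Peak Oxygen-Uptake Prediction Equations for
    Cardiopulmonary Exercise Testing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing commonly used peak oxygen uptake (VO2peak)
    prediction equations in cardiopulmonary exercise testing (CPET). Implements
    six reference equations (FRIEND, Wasserman, Hansen, Bruce, Jones, Neder)
    with an editable coefficient registry, ideal-body-weight logic and a
    cycle/treadmill modality correction; percent-predicted classification of
    exercise capacity at a fixed threshold; agreement statistics between
    equations (Cohen's kappa with interpretation bands, bidirectional
    reclassification, absolute-difference quartiles, Friedman test with
    Kendall's W effect size and all-pairs post hoc comparisons); multivariable
    regression of inter-equation differences on scaled demographic covariates;
    weight and age sweep curves with ideal-weight markers; standard CPET
    derived variables and disability cut-off flags; and a reproducible
    synthetic cohort generator for end-to-end pipeline testing when clinical
    data cannot be shared.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    jsonlite
Config/testthat/edition: 3
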
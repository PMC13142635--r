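Package: canid
Title: Scoring and Longitudinal Evaluation of the CANID Canine Cognitive Test Battery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for scoring the CANID (Cognitive Assessment for
    Neuropsychological Impairments in Dogs) behavioral battery and for
    evaluating its psychometric properties in longitudinal designs.
    Provides deterministic trial-level scorers for the Spatial Reversal,
    Delayed Search, and Cylinder tasks; a baseline-fitted composite scoring
    model (task-level principal components, Yeo-Johnson normalization,
    regression-based single-task imputation, and an overall first-component
    score) with out-of-sample projection of follow-up sessions into the
    baseline component space; repeatability estimation via pairwise,
    intercept-only, and covariate-adjusted intraclass correlation
    coefficients with parametric bootstrap confidence intervals; linear
    mixed-effects aging models with orthogonal polynomial age terms,
    practice-effect contrasts, and likelihood-ratio age effect sizes; and a
    protocol-faithful behavioral simulator with known ground truth for
    validating the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    graphics,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    car,
    withr
Config/testthat/edition: 3
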
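Package: threemode
Title: Three-Mode Principal Component Analysis for Longitudinal Symptom Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Decomposes longitudinal item-level questionnaire data
    (persons x items x time points) with three-mode principal component
    analysis (Tucker3), fitted by alternating least squares. Provides the
    full analysis pipeline for incomplete repeated-measures symptom data:
    bootstrap-EM multivariate-normal multiple imputation, fixed-effects
    three-way ANOVA variance decomposition, person-mode centering and
    symptom-mode normalization, generalized scree model selection with
    split-half stability, Joint Orthomax rotation of core and component
    matrices, generalized Procrustes pooling across imputations, and
    interpretation tables (core explained variance, component trajectories,
    external correlations). Includes a synthetic-data generator with planted
    Tucker3 structure for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
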
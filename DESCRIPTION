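Package: cogdx
Title: Diagnostic Accuracy Analysis for Computerized Cognitive Test Batteries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Validation toolkit for composite cognitive screening batteries
    scored against a normative database. Implements battery scoring with
    age- and device-stratified z-standardization and time-out penalties,
    covariate-adjusted three-group comparison (normal cognition, mild
    cognitive impairment, dementia) with Tukey-adjusted contrasts of
    estimated marginal means, binary ROC analysis with Youden-optimal
    cutoffs, three-class ROC-surface classification (volume under the
    surface and optimal cutoff pairs), and a calibrated synthetic cohort
    simulator for end-to-end testing of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    emmeans,
    jsonlite,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
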
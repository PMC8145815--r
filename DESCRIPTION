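Package: equidecomp
Title: Concentration Indices, Decomposition and Horizontal Inequity for
    Health Services Utilization Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for measuring income-related inequality in binary
    health services utilization outcomes from respondent-level survey
    extracts. Computes weighted fractional income ranks, concentration
    curves and concentration indices with convenient-regression
    (heteroskedasticity- and cluster-robust) confidence limits,
    regression-based decomposition of the index into determinant
    contributions, and the horizontal inequity index obtained by
    removing the contribution of need variables. Includes a descriptive
    layer (utilization rates with Wilson confidence limits, Pearson
    chi-square contingency tables, sample composition tables), a
    random-intercept logistic outcome model with average marginal
    effects, a synthetic survey-data generator with known ground-truth
    inequality structure, and an end-to-end study pipeline stratified
    by policy period.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    lme4,
    sandwich,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
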
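Package: qsarens
Title: Bayesian Ensemble Classification for QSAR Carcinogenicity Panels
Version: 0.1.0
Authors@R:
    person("Panel", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Combines binary carcinogenicity calls from multiple QSAR
    (quantitative structure-activity relationship) tools into a single
    classifier by estimating, from a training panel, the empirical
    posterior probability of carcinogenicity for each of the 2^m possible
    prediction combinations, and thresholding that posterior against a
    variable cut-off. Ships the full validation protocol for such panels:
    leave-one-out cross-validation, confusion-matrix statistics
    (accuracy, sensitivity, specificity, balanced accuracy, PPV, NPV),
    Cohen's kappa, ROC curves traced over a cut-off grid, and paired
    significance tests against AND/OR/majority consensus baselines and
    single tools. Includes a seeded simulator of correlated binary
    classifier panels with a closed-form posterior oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
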
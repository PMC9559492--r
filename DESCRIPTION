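Package: panelsense
Title: Drug-Sensitivity Endpoints, Expression Biomarkers and Synergy Scoring
    for Cell-Line Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for cell-line panel drug screens: constrained
    four-parameter logistic dose-response fitting with a standard-error-based
    quality rule and closed-form area-under-curve endpoints; z-score
    sensitivity classification; low-expression filtering and Spearman
    screening of log2(FPKM) expression matrices against panel endpoints;
    shadow-feature (Boruta-style) signature-gene selection with a linear
    predictor score / Bayes posterior classifier evaluated by repeated
    stratified cross-validation; highest-single-agent synergy delta scoring of
    dose-combination matrices; and downstream assay quantification (delta-delta
    Ct relative expression, comet-assay percent crosslinks). Includes seeded
    synthetic-data generators that emulate the statistical structure of such
    panels for calibration and recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    ranger,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
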
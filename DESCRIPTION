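Package: iohponv
Title: Intraoperative Hypotension Characterization and Its Association
    with Postoperative Nausea and Vomiting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for characterizing intraoperative hypotension (IOH) from
    perioperative blood-pressure records and estimating its association with
    postoperative nausea and vomiting (PONV) in clustered surgical cohorts.
    Implements rule-based blood-pressure artifact removal and linear
    interpolation to a uniform 15-second mean-arterial-pressure grid; the
    standard family of IOH exposure characterizations (lowest sustained and
    cumulative MAP over 1-15 minutes, absolute and relative time under
    thresholds of 50-80 mmHg); generalized estimating equation (GEE)
    logistic regression with an exchangeable working correlation, natural
    cubic spline bases and robust (sandwich) covariance; cluster-respecting
    repeated k-fold cross-validation with Brier score, c-statistic,
    discrimination slope and calibration slope; Brier-score model selection
    across characterizations on a shaping split and delta-method adjusted
    odds-ratio estimation on an independent estimation split; and a
    synthetic perioperative cohort generator for testing the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    splines,
    utils,
    zoo,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
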
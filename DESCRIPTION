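Package: lcurve
Title: Learning-Curve Analysis for Sequential Surgical Outcomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Cumulative summation (CUSUM) analysis of consecutive binary
    surgical outcomes against fixed reference failure rates, with
    learning-curve endpoint detection, per-operator slope estimation and
    comparison, experience-group contingency statistics (chi-square,
    Mantel-Haenszel linear-by-linear trend, Kruskal-Wallis), crude and
    covariate-adjusted logistic odds ratios, and restricted-cubic-spline
    dose-response modelling with a likelihood-ratio test for nonlinearity.
    Includes a seeded simulator of operator outcome sequences with a
    tunable learning process and a deterministic multicentre cohort
    fixture, so the full pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
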
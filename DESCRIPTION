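Package: natfreq
Title: Natural Frequencies and Population Diagrams for Clinical Prediction Rules
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for communicating the trade-offs of clinical prediction
    rules using natural frequencies. Converts rule performance (sensitivity,
    specificity, prevalence) at one or more cut-points into whole-person 2x2
    counts on a reference population, renders population diagrams (icon
    arrays with two-way coding of event status and rule classification) as
    deterministic SVG, tabulates trade-offs across cut-points and
    prevalences, and computes the conventional companions: predictive
    values, the C-statistic, and decision-curve net benefit. Includes a
    binormal risk-score simulator with a closed-form link between score
    separation and the C-statistic, and packaged case-study fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    xml2,
    optparse
Config/testthat/edition: 3
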
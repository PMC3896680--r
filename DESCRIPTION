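Package: dcvkit
Title: Discriminant Content Validity Analysis for Questionnaire Items
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discriminant content validity (DCV) studies, in which
    expert judges allocate questionnaire items to theoretical domains with
    confidence ratings. Implements confidence-weighted judgment scoring,
    one-tailed one-sample t-tests with Benjamini-Hochberg false discovery rate
    control, the pure/mixed/misclassified item taxonomy and final-item
    selection, multi-rater agreement via Cohen's and Light's kappa with
    bootstrap confidence intervals, a bilingual Theoretical Domains Framework
    (TDF) item bank with TACT-style placeholder templating, and a synthetic
    judge-data generator for validating the pipeline end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
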
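Package: drtestset
Title: Standardized Test-Set Construction and Algorithm Evaluation for
    Diabetic Retinopathy Grading
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates and evaluates the construction of standardized,
    label-level test sets for computer-aided diabetic retinopathy (DR)
    grading. Provides a seven-class (ICDR-style) cohort simulator with
    confusion-matrix annotators and raw hospital labels, a qualification-exam
    module for annotator admission, a two-round reference-standard
    adjudication workflow (blinded triple annotation, sampled inspection,
    senior arbitration, provenance accounting), rater-agreement statistics
    (Fleiss and Cohen kappa, intraclass correlation), and per-class
    diagnostic evaluation of algorithms under test, including the exact
    reconstruction of overall sensitivity, specificity and accuracy from
    per-class decision capabilities and cohort composition.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
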
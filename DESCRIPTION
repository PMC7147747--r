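Package: drscreen
Title: Decision Policies, Quality Curation and Screening Metrics for Diabetic Retinopathy Grading
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the post-classifier stages of an automated diabetic
    retinopathy (DR) screening pipeline: remapping of the five-grade fundus
    labelling scheme to referable/non-referable and healthy/diseased schemes
    with deterministic stratified splitting; Gaussian-blur-subtraction contrast
    enhancement of fundus photographs with crop and resize; image-adequacy
    scoring and curated-subset generation through a pluggable scorer registry;
    sensitivity-boosting decision rules (argmax, cascading thresholds, margin
    max) applied to classifier probability vectors; one-vs-rest screening
    metrics (sensitivity, specificity, PPV, NPV, F1, accuracy); and seeded
    synthetic generators for probability records and fundus-like images so
    every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
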
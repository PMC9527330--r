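Package: fferg
Title: Full-Field Electroretinogram Phenotyping and Variant Severity Scoring
Version: 0.9.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: End-to-end analysis pipeline for ISCEV-standard full-field
    electroretinograms (DA 10, LA 3 and LA 30 Hz flicker) in ABCA4
    retinopathy. Provides automated repeat-trace selection, Butterworth
    filtered zero-crossing detection of a-wave, b-wave and flicker-peak
    components, a hierarchical soft-voting ensemble classifier of the three
    functional phenotype groups evaluated by repeated nested cross-validation,
    elastic-net scoring of per-variant severity from biallelic genotypes, and
    a synthetic-cohort generator with known ground truth for testing every
    stage without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
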
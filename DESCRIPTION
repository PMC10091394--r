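Package: gdtec
Title: Genome-Driven Transcriptome Fusion for Cancer Subtyping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discretizes somatic mutation, copy-number and tumor-versus-normal
    expression-change profiles per gene and patient, fuses them with
    consistency rules into a binary genome-driven transcriptome expression
    (GDTEC) matrix, identifies molecular subtypes by resampling consensus
    clustering with CDF/delta-area k selection and a robustness battery,
    and builds Cox proportional-hazards risk models and random-forest
    subtype classifiers on the fused features. Includes a synthetic
    multi-omics cohort generator with planted subtype structure and
    survival effects so the whole pipeline is testable without external
    cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    survival,
    cluster,
    randomForest,
    pROC,
    mclust,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
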
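Package: oasig
Title: Blood Gene-Expression Signature Discovery via mRMR and Incremental Feature Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers compact case/control gene-expression signatures from
    blood transcriptome matrices. Implements probe-to-gene collapsing and
    quantile normalization, mean +/- SD three-level discretization, plug-in
    mutual-information estimation, greedy minimal-redundancy
    maximal-relevance (mRMR) gene ranking, incremental feature selection
    with a radial-kernel SVM evaluated by leave-one-out cross-validation,
    Matthews-correlation-based signature selection, and post-hoc signature
    statistics (hypergeometric set-overlap enrichment and per-gene class
    direction). Includes a seeded synthetic-cohort generator with known
    ground truth so the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    e1071,
    limma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
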
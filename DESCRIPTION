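Package: rgife
Title: Ranked-Guided Iterative Feature Elimination for Biomarker Signatures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies minimal, highly predictive biomarker signatures from
    class-labelled omics matrices by iteratively removing blocks of
    low-importance features ranked by a random forest, with back-tracking,
    soft-fail acceptance and a decaying relative block size. Includes
    distribution-balanced stratified cross-validation (DB-SCV), seeded
    generators for classic feature-selection benchmark datasets (CorrAL,
    XOR-100, Parity3+3, Monk3, SD1-SD3, two-condition microarray,
    Madelon-like), multi-classifier signature evaluation, and scoring of
    selected feature sets with the Success Index and set-overlap metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    foreign,
    ranger,
    e1071,
    class,
    yaml,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
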
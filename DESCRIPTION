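Package: ctsclock
Title: Cell-Type Specific Epigenetic Clocks from Bulk DNA Methylation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Build and evaluate cell-type specific epigenetic clocks from
    bulk DNA methylation data. Provides reference-based estimation of
    cell-type fractions (robust IRLS or non-negative least squares),
    detection of cell-type specific age-associated CpGs through an
    interaction regression between age and cell-type fractions, training
    of intrinsic and semi-intrinsic elastic-net age predictors with
    external or cross-validated penalty selection, a stratified 10-bag
    nested cross-validation procedure with per-fold marker re-discovery,
    decomposition of clock accuracy into intrinsic and extrinsic
    (cell-composition driven) components, inverse-variance meta-analysis
    and enrichment utilities, and a fully parameterized mixture simulator
    for benchmarking the intrinsic versus semi-intrinsic clock designs.
License: MIT
Encoding: UTF-8
Imports:
    glmnet,
    jsonlite,
    pracma,
    stats,
    tools,
    utils
Suggests:
    metafor,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
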
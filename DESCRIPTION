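Package: transprot
Title: Cross-Omics Translation of Bulk Transcriptomes into Predicted Proteomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts per-sample protein abundance from bulk transcriptome
    features (mRNA, pre-mRNA, normalized 3'UTR length) with an ensemble of
    variational encoder-decoder submodels, each merged per protein with the
    gene's own transcript features through a linear-regression layer.
    Includes leak-safe feature-space construction, stratified out-of-fold
    cross-validation, expected-gradient input attribution with
    per-component contribution removal, covariate-adjusted trait
    association with multiple-testing correction, proteome pseudotime by
    spectral embedding and principal-path fitting, LOESS-based
    early/mid/late module staging, and LMG variance decomposition. A
    synthetic paired multi-omics generator with a planted one-dimensional
    disease progression provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
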
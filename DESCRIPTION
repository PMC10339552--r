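Package: enhancerScan
Title: Enhancer Identification and Strength Classification with
    Dual-Scale Convolution and Spatial Attention
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A two-layer sequence-based predictor of enhancers and their
    strength. DNA sequences are tokenized into overlapping 3-mers and
    embedded with a skip-gram word-embedding model trained by negative
    sampling; features are extracted by two parallel 1D convolutions with
    kernel widths 10 and 12 whose rectified outputs are fused along the
    spatial axis, re-weighted by a spatial attention gate computed from
    channel-pooled summaries, globally max-pooled and classified by a
    two-way softmax head trained with Adam on the cross-entropy loss.
    Includes evaluation metrics (ACC, MCC, SN, SP, AUC), stratified
    k-fold cross-validation with leakage-safe per-fold embedding
    retraining, multi-seed stability analysis, ablation variants, a
    planted-motif synthetic sequence generator with BED-like ground
    truth, and a command-line interface for reproducible runs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    BiocGenerics,
    jsonlite,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
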
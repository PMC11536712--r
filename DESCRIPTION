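Package: bcrclone
Title: Joint BCR Hyperclustering and Tumour Clone Assignment from
    Single-Cell Variant Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Nonparametric Bayesian joint clustering of tumour B cells by
    their B-cell receptor (BCR) nucleotide sequences and probabilistic
    assignment of the resulting hyperclusters to exome-derived tumour
    clones, using alternate and total UMI counts at somatic SNV positions
    from single-cell RNA sequencing.  Hyperclusters follow a Chinese
    Restaurant Process prior with per-position nucleotide frequency
    profiles; the input clone genotype matrix is treated as error-prone and
    corrected through an explicit error model.  Provides a full Gibbs
    sampler with auxiliary-variable resampling of the concentration
    parameter, multi-chain convergence assessment, a simulation framework
    with known ground truth, and evaluation metrics (cell-to-clone
    assignment accuracy, genotype reconstruction accuracy, adjusted Rand
    index, assignment entropy).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    mclust,
    ape,
    yaml,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    coda,
    withr,
    Biostrings
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
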
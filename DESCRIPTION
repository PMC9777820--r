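Package: mirsite
Title: miRNA Target-Site Binding Prediction from Watson-Crick Binding Matrices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Toolkit for scoring the binding potential of miRNA:target-site
    pairs. Encodes a 20-nt miRNA against a 50-nt target window as a 20 x 50
    binary matrix of Watson-Crick complementarity indicators and scores it
    with small convolutional or residual neural networks trained with the
    Adam optimizer on binary cross-entropy, optionally against soft labels
    produced by instance-hardness label smoothing of the negative class.
    Includes construction of shuffled-negative datasets at controlled
    positive:negative ratios, a canonical 2-7 seed-match heuristic and
    free-energy score normalization as baselines, precision-recall and ROC
    evaluation suited to heavy class imbalance, a synthetic-data generator
    with planted binding mechanisms, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    grDevices,
    graphics,
    methods,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    pROC,
    rtracklayer,
    GenomicRanges
LinkingTo: Rcpp, RcppArmadillo
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
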
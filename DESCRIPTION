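Package: DisorderCNF
Title: Weighted Deep Convolutional Neural Fields for Protein
    Order/Disorder Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Predicts intrinsically disordered protein regions with a
    weighted deep convolutional neural field: a stack of position-shared
    convolutional layers feeds a linear-chain conditional random field
    whose emission and transition potentials carry per-label weights to
    counter the strong order/disorder class imbalance. Provides the
    129-dimensional per-residue feature construction from sequence,
    evolutionary profiles (PSI-BLAST PSSM, HH-suite HHM) and predicted
    local structure, CASP-convention disorder labeling from
    missing-coordinate annotations, exact maximum-likelihood training by
    L-BFGS with L2 regularization, forward-backward inference in log
    space, ROC/AUC/MCC/balanced-accuracy evaluation, a seeded synthetic
    corpus generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
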
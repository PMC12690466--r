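Package: essnet
Title: Inductive Subgraph Sampling for Essential Gene Prediction on
    Protein-Protein Interaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts gene essentiality from protein-protein interaction
    networks and expression-derived node features with an inductive
    sample-and-aggregate graph neural network.  Includes construction of
    essential/nonessential/unlabeled gene labels from knockout-screen
    gene-effect matrices via percentile ranking and kernel-density valley
    thresholding, PCA-based node featurization with inductive projection of
    unseen genes, class-imbalance-aware cross-validated evaluation
    (AUPRC, AUROC, Youden's J), controlled perturbation of network structure
    and node features, and synthetic-data generators emulating scale-free
    interaction networks, expression matrices with planted class signal, and
    bimodal gene-effect screens.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
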
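Package: dagformer
Title: Graph-Based Domain Adaptation for Single-Cell Drug Response Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Transfers drug-response labels from bulk RNA-seq cell-line data to
    unlabeled single-cell RNA-seq data. Builds cellular neighbor graphs
    (Spearman, Pearson or cosine-KNN), encodes both domains with private and
    shared graph-transformer encoders whose attention is sparsified by the
    graph, reconstructs each graph with an inner-product decoder, and aligns
    the shared representation across domains adversarially through a gradient
    reversal layer and domain discriminator. A linear predictor trained with
    source cross-entropy and target entropy minimization yields per-cell
    sensitivity probabilities. Includes preprocessing (quality control,
    normalization, SMOTE plus random undersampling, gene intersection), a
    two-domain synthetic data generator, a full-batch adversarial training
    loop with hold-out and ablation protocols, and ACC/AUC/AUPR evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    Rcpp,
    data.table,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
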
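Package: deepm5U
Title: Deep Learning Classification and Interpretation of RNA 5-Methyluridine Sites
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies RNA 5-methyluridine (m5U) sites from 41-nt sequence
    windows with convolutional and bidirectional recurrent neural networks
    (CNN, BiLSTM, BiGRU, CNN-BiLSTM, CNN-BiGRU) trained as 5-member averaged
    ensembles, and interprets the trained models with layer-wise UMAP
    projections, Shapley-value attribution accumulated into sequence-logo
    matrices, and in-silico saturation mutagenesis.  Includes a planted-motif
    synthetic benchmark generator, a full binary-classification metric suite
    (accuracy, precision, recall, F-value, MCC, ROC/PR curves and areas), and
    a command-line workflow (simulate / train / predict / evaluate / umap /
    shap / mutate).  The sequence-model engine is implemented in
    Rcpp/RcppArmadillo.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    cluster,
    withr,
    optparse,
    Biostrings
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC
SystemRequirements: C++17; Python (>= 3.8) with numpy and umap-learn on the
    PATH for UMAP layer projection.
Config/testthat/edition: 3
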
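Package: sulfsite
Title: Prediction of Cysteine S-Sulfhydration Sites with an
    Entropy-Weighted Transformer Encoder and Directional GRUs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for predicting S-sulfhydration (persulfidation) sites on
    protein cysteines from primary sequence. Extracts fixed-length
    Cys-centered windows, segments them into left/right/full parts under
    configurable reading orientations, embeds residues with a
    masked-language-model transformer encoder whose per-layer outputs are
    aggregated by information-entropy weights, removes probable mislabeled
    negatives by confident learning, and classifies sites with a
    three-branch directional GRU followed by multi-head self-attention, a
    1-D convolutional feature extractor and a sigmoid head. Includes
    stratified protein-grouped cross-validation, the standard
    site-prediction metrics (Sn, Sp, Pre, Acc, MCC, AUC), a direction-code
    ablation harness, and a synthetic planted-motif window generator for
    end-to-end testing without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
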
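Package: hypersyn
Title: Hypergraph Neural Networks for Anti-Cancer Drug Synergy Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts synergistic effects of anti-cancer drug combinations by
    integrating drug chemical structures, cell-line gene expression, and
    drug-disease indication knowledge in a dual-relationship hypergraph.
    Drugs are encoded from SMILES via molecular graphs refined by a
    multi-head graph-transformer stack with max-pooling readout; cell lines
    and diseases are mapped into the common feature space by single-layer
    perceptron encoders. Node features are refined by degree-normalized
    hypergraph convolutions with gated residual connections and equilibrium
    bias initialization, and drug-drug-cell-line triplets are scored by a
    sigmoid classifier trained with symmetric permutation augmentation and
    cross-entropy loss. Includes five cross-validation stratification
    strategies (random, cell-line, drug-combination, single-novel-drug,
    double-novel-drug), threshold-free ranking metrics, and a synthetic
    cohort generator with a plantable synergy signal for desk-scale testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    ChemmineR,
    ChemmineOB,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml,
    optparse,
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
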
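Package: aptaml
Title: Aptamer-Protein Interaction Prediction from Sequence-Derived Features
Version: 0.1.0
Authors@R:
    person("Aptaml", "Developers", email = "aptaml@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for predicting aptamer-protein
    interactions from primary sequence alone. Aptamers (DNA, or RNA
    converted U to T) are encoded as cumulative k-mer and
    reverse-complement canonical k-mer window frequencies; target
    proteins are encoded as amino acid composition (AAC) and pseudo
    amino acid composition (PseAAC) over standardized physicochemical
    property triples. Class imbalance is handled by the Neighborhood
    Cleaning rule (Wilson's edited nearest neighbour vote) or random
    undersampling, features are ranked by random-forest Gini importance,
    and a seven-layer multilayer perceptron with dropout is trained
    under binary cross-entropy. Includes a synthetic interaction-data
    generator with plantable k-mer and composition signal, stratified
    cross-validation with confusion-matrix metrics (MCC, F1,
    sensitivity, specificity) and ROC/AUC, and a command-line
    orchestrator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    FNN,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    Biostrings
Config/testthat/edition: 3
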
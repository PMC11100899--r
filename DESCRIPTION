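Package: nfscreen
Title: Neural Fingerprint-Based Virtual Screening of Docked Compound Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains a differentiable graph-convolutional molecular
    fingerprint jointly with a neural binary classifier to predict whether a
    molecule's docking-derived binding free energy falls below a percentile
    threshold. The fingerprint replaces the hash and array-indexing steps of
    the circular (Morgan/ECFP) algorithm with sigmoid and softmax maps, so
    the loss gradient trains the molecular representation end to end.
    Includes score-table ingestion with percentile thresholding and 70/15/15
    splitting, minority-class oversampling, hyperparameter grid search,
    screening metrics (precision, recall, F1, ROC-AUC, PR-AUC, predictive
    enrichment probability), a fixed Morgan-fingerprint baseline for
    architecture comparison, and a synthetic docking-score generator.
    SMILES handling is delegated to RDKit through a batch subprocess bridge.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
SystemRequirements: Python (>= 3.8) with RDKit, available as 'python' on
    the PATH (override with the NFSCREEN_PYTHON environment variable).
Config/testthat/edition: 3
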
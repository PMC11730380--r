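Package: ddilearn
Title: Drug-Drug Interaction Prediction by Multi-View Feature Projection
    with Relation Regularization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts drug-drug interactions (DDIs) from multiple binary
    drug-feature tables (pathways, enzymes, targets, chemical
    substructures) by projecting each feature space into a common
    interaction space with non-negative multiplicative updates, and
    regularizing predicted scores with a self-representation structure
    learned from the known interaction network.  Supports both scoring of
    unobserved pairs among networked drugs and cold-start prediction for
    drugs outside the network, five-fold cross-validation with AUPR as
    the primary metric, a synthetic benchmark generator with plantable
    low-rank structure, and severity grading of predicted interactions
    via weighted molecular-fingerprint similarity computed from SMILES.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    methods,
    stats,
    utils,
    yaml,
    ChemmineR,
    ChemmineOB
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
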
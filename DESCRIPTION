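Package: ppinet
Title: Predictive Pharmacointeraction Networks for Drug-Drug Interaction
    Link Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds undirected, severity-labelled drug-drug interaction
    (DDI) networks from edge-list snapshots, derives network, taxonomic and
    chemical-substructure covariates for drug pairs, fits univariate and
    multivariate logistic models as well as drug-specific random-intercept
    mixed models to score unknown pairs, and evaluates predictions by a
    simulated-prospective protocol between two chronological snapshots
    (ROC/AUROC, operating points at benchmark specificities, lift,
    prediction-set overlap, and a high-specificity threshold-intersection
    heuristic). Includes a synthetic-data generator with planted taxonomy,
    fingerprint and degree-heterogeneity structure so the whole pipeline is
    testable without proprietary drug-safety data, and a basic
    interaction-type suggestion method based on neighborhood type
    frequencies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    lme4,
    pROC,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
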
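Package: doepred
Title: Direction-of-Effect Prediction for Drug Targets from Genetic Evidence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the direction of effect (DOE) for drug targets -- whether
    therapeutic benefit requires activating or inhibiting a gene product -- at
    the gene level and the gene-disease level. Unifies drug mechanism
    annotations across sources with a disjoint-set identifier graph, assembles
    gene-level design matrices from tabular features plus truncated gene
    embeddings and PCA-reduced protein embeddings, encodes signed genetic
    evidence (signed -log10 p GWAS, eQTL direction concordance, rare-variant
    functional classes, gene-burden tests) into gene-disease feature vectors,
    trains one-vs-rest gradient-boosted models under nested eightfold
    cross-validation with inner-fold prediction averaging, and evaluates with
    AUROC, reverse-percentile bootstrap confidence intervals, calibration
    curves, and F-beta-optimal cutoffs. Includes a synthetic-data generator
    emulating the statistical structure of multi-source drug catalogs and
    sparse genetic association evidence with configurable planted signal.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    xgboost,
    jsonlite
Suggests: testthat (>= 3.0.0), pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
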
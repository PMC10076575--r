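Package: hergml
Title: Ligand- and Structure-Based Random Forest Classification of hERG
    Channel Liability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Workflow for building and comparing ligand-based and
    structure-based (docking pose-score) Random Forest classifiers of hERG
    potassium-channel liability. Curates raw activity tables to binary
    binder labels (pK >= 5), computes physicochemical and hashed circular
    fingerprint descriptor blocks, aggregates multi-engine multi-pose
    docking score tables by best-pose or binding-space average strategies,
    performs correlation-based feature-subset selection with best-first
    search, trains and cross-validates classifiers with consensus voting,
    and assesses applicability domain by a four-method consensus
    (fingerprint similarity, PCA range, centroid distance, probability
    density). A synthetic cohort generator built on a closed fragment
    grammar emulates activity databases and docking engine output so the
    whole pipeline is testable without proprietary data or docking
    software.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    ChemmineR,
    ChemmineOB,
    ranger,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse,
    knitr
SystemRequirements: OpenBabel (obabel on the PATH)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
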
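Package: diliqsar
Title: QSAR Modeling of Drug-Induced Liver Injury with a Voting-Filtered
    Eight-Classifier Ensemble
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A complete QSAR workflow for binary hepatotoxicity (drug-induced
    liver injury, DILI) prediction from molecular structures: structure
    standardization and admission filters, an 85-descriptor feature block with
    FP2 path fingerprints and Tanimoto diversity summaries, near-constant and
    correlation feature filters, Kennard-Stone subset selection for class
    balancing, a cross-validated voting filter that removes probable
    mislabeled training compounds, an eight-classifier probability-averaging
    ensemble evaluated under stratified 10-fold cross-validation, and
    Y-randomization for chance-level validation. Synthetic labeled datasets
    with controllable class signal, feature redundancy and label noise make
    every stage testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ChemmineR,
    ChemmineOB,
    class,
    e1071,
    graphics,
    igraph,
    jsonlite,
    nnet,
    randomForest,
    rpart,
    stats,
    tools,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
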
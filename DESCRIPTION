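Package: ubppred
Title: Sequence-Based Prediction of Ubiquinone-Binding Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies ubiquinone-binding proteins (UBPs) from primary
    sequence. Encodes proteins as 820-dimensional vectors (amino acid
    composition, dipeptide composition and PSSM composition computed from
    PSI-BLAST evolutionary profiles), ranks features by random-forest Gini
    importance with incremental feature selection, classifies with a
    gradient-boosted tree model whose eight hyperparameters are tuned by
    multi-objective particle swarm optimization, and evaluates with a
    six-metric confusion-matrix suite under stratified cross-validation.
    Also provides hypergeometric GO/KEGG term enrichment, extraction of
    21-residue binding-site windows for motif discovery, and a synthetic
    data generator for planted-signal benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    randomForest,
    stats,
    tools,
    utils,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
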
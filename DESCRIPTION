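Package: yeastpgx
Title: Projecting Yeast Chemogenomic Profiles onto Human Pharmacogenomic
    Associations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores candidate human drug-gene (pharmacogenomic)
    associations by projecting genome-scale yeast HIP/HOP chemogenomic
    fitness screens across species. The core statistic is the maximal
    geometric mean of drug similarity (chemical Tanimoto or ATC
    hierarchy), cross-species gene similarity (alignment coverage or
    domain Jaccard), and the normalized chemogenomic response, taken over
    all screened drug-gene pairs. A Random Forest combines 24 such
    features (eight per screen source) into an association probability.
    Includes negative-pair samplers (uniform and conservation-matched),
    repeated stratified cross-validation with class-imbalance sweeps,
    external association-matrix ROC validation, hypergeometric
    enrichment, two comparison baselines (known-association human-only
    similarity and a PPI-neighbour method), and a synthetic-corpus
    generator with planted signal so the full pipeline is testable
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    generics,
    ggplot2,
    Matrix,
    methods,
    pROC,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    ChemmineR,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
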
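Package: mirPathNet
Title: miRNA Regulators of Discriminative Pathway-Pair Networks in Basal
    Breast Cancer
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Identifies microRNAs with high degree centrality over a network
    of pathway pairs that discriminate basal (triple-negative-like) breast
    tumors from normal tissue. The pipeline proceeds in six steps:
    differential expression between tumor and normal samples, Fisher exact
    pathway enrichment, per-sample pathway-pair discriminating scores,
    Random Forest classification under Monte Carlo cross-validation with
    class balancing and AUC-based selection of the top pathway pairs, and
    integration of miRNA expression via mutual information and Fisher's
    exact test, summarised per miRNA as degree centrality. A synthetic
    cohort generator with planted differential expression and planted
    miRNA regulators makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    randomForest,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
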
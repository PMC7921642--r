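Package: stageSigNet
Title: Stage Signatures and Network Gatekeepers for Carcinogenesis
    Expression Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Discovery of stage-discriminative gene signatures in an
    ordered eight-stage carcinogenesis expression series. Implements
    per-stage differential expression against a pooled control group with
    empirical-Bayes moderated t-statistics, Benjamini-Hochberg adjustment
    and signed fold-change filtering; cleaning of protein-protein
    interaction edge lists and detection of network "gatekeepers" (nodes
    whose clustering centrality equals one, bridging interconnected
    hubs); two-round standardized-coefficient reduction of a multinomial
    logistic stage classifier with a random-signature Jaccard null; and
    Fisher exact over/under-representation of gene lists against gene-set
    collections. A seeded synthetic-data module generates expression
    matrices with planted stage signatures and interactomes with planted
    hubs and gatekeepers so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    igraph,
    jsonlite,
    Matrix,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    limma,
    glmnet,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
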
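Package: evhub
Title: Prediction of Metastasis-Relevant Hub Genes from Extracellular-Vesicle miRNA Cargo
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-branch pipeline for predicting candidate hub genes from
    differential extracellular-vesicle (EV) miRNA expression. Differentially
    loaded miRNAs are selected by a volcano filter and top-k fold-change
    ranking, mapped to target genes through TargetScan-style context-score
    tables thresholded on the cumulative weighted context++ score, and the
    pooled target sets are analysed along two routes: a global branch that
    ranks genes in a STRING-style protein-interaction network by maximal
    clique centrality (MCC) and degree, and a specific-keyword branch that
    matches a curated immune/inflammation lexicon against gene annotation
    text and selects genes by bipartite degree. Candidates from both branches
    are merged into a report carrying each gene's regulating miRNA and the
    inferred direction of gene regulation. Seeded synthetic-data generators
    (negative-binomial counts with planted fold changes, target tables with
    controlled overlap, interaction graphs with planted cliques, annotation
    corpora with planted keywords) make every stage testable without external
    downloads, and a small assay-metrics module provides LDH cytotoxicity,
    phagocytic-activity and invasion-count quantification plus Smirnoff-Grubbs
    outlier screening and two-sample t utilities.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
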
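Package: cardioNet
Title: Network-Based Discovery of Early Transcriptional Responses to Cardiac Injury
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrative pipeline for identifying genes with robust early
    transcriptional responses to cardiac injury from time-course expression
    data, modelled on the zebrafish heart-regeneration setting. Implements
    empirical-Bayes moderated differential expression with time-point
    contrasts, co-expression networks gated by Pearson correlation and the
    maximal information coefficient, three independent network analyses
    (overlapping cohesive modules, model-tree directed association networks,
    and weighted topological-overlap modules with eigengene merging),
    cross-dataset concordance of expression profiles and fold changes, and
    efficiency-corrected multi-reference qPCR fold-change validation. A
    synthetic time-course generator with planted ground truth exercises every
    stage without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    limma,
    igraph,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    jsonlite,
    optparse
biocViews: GeneExpression, Network, TimeCourse, DifferentialExpression,
    NetworkInference, GraphAndNetwork, qPCR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
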
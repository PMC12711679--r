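Package: implinet
Title: Boolean Implication Networks for Transcriptome Discretization,
    Clustering and Composite-Score Stratification
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Infers Boolean implication networks from log2 gene expression
    matrices.  Genes are discretized with a one-step (StepMiner-style) fit
    plus a noise margin, pairwise implication relationships are detected from
    sparsely populated quadrants of the joint Boolean scatter, equivalent
    genes are clustered by minimum-spanning-tree construction with Jaccard
    pruning into a directed cluster-level network, and Boolean paths are
    charted from seed genes.  Samples are ordered, classified and stratified
    for survival with weighted threshold-normalized composite signature
    scores.  A synthetic-data module plants implication DAGs with known
    ground truth so the whole pipeline is testable without external cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    data.table,
    igraph,
    jsonlite,
    survival
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
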
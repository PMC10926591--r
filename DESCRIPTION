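Package: puffin
Title: Guilt-by-Association and Structural Transfer of Gene Ontology
    Annotations to Proteins of Unknown Function
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-arm pipeline for predicting Gene Ontology (GO) annotations
    of proteins of unknown function (PUFs) from integrated multi-omics
    similarity evidence. The guilt-by-association arm learns the depth of the
    deepest shared GO term for within-species protein pairs from ~20
    similarity measures (sequence motifs, bitscores, operon co-membership,
    evolutionary correlations, proteomic co-expression, structure alignment
    and STRING sub-scores), thresholds predictions into a hit network, and
    transfers terms from hits via a positive/unlabeled candidate classifier
    calibrated to a target false discovery rate on a deliberately unlabeled
    holdout. The structural arm applies the same transfer engine to
    structure-search hits filtered by TM-score, with global-alignment and
    taxonomic-rank predictors. Downstream analyses quantify functional
    coherence as binary-partition network modularity against random and
    GO-term partitions, and fit Bayesian hierarchical models for term
    enrichment (odds ratios partially pooled across term depths) and expected
    PUF counts. A synthetic-data module generates every input with a planted
    functional signal and masked ground truth so the whole pipeline is
    testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    Rcpp,
    methods,
    stats,
    utils,
    igraph,
    ranger,
    rjags,
    coda,
    jsonlite,
    Biostrings,
    bio3d
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
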
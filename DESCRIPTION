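Package: histoneBN
Title: Consensus Bayesian Networks of Combinatorial Histone-Modification
    Patterns
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis of combinatorial histone-modification patterns in
    exon-skipping events from binary (present/absent) ChIP-seq calls.
    Computes pairwise phi (Pearson) correlations between modifications,
    learns Bayesian-network structure over binary marks with a
    score-based (BDeu/BIC) hill-climbing search and an exhaustive-search
    oracle for small node counts, builds consensus networks from ten
    leave-one-fold-out learners with an edge-stability filter, and
    compares the resulting networks between splicing classes and exon
    flanking regions. Includes a seeded synthetic-data generator
    (planted DAGs with conditional probability tables and a
    histone-like preset) so the full pipeline is testable without the
    original CD4+ T-cell matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    grid,
    igraph,
    jsonlite,
    pheatmap,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'accessors.R'
    'catalog.R'
    'io.R'
    'synthetic.R'
    'correlation.R'
    'score.R'
    'hillclimb.R'
    'exhaustive.R'
    'consensus.R'
    'netcompare.R'
    'pipeline.R'
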
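Package: stateQTL
Title: Molecular Network State Scoring and Classification of QTL Effects in Yeast Crosses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying global molecular network states in segregant
    yeast crosses and classifying genetic variant effects as local, regional, or
    global. Implements signature derivation from kinase-inhibition profiles and
    median-difference state scoring, Random-Forest QTL mapping with permutation
    false-discovery control, coordination tests against abundance-matched nulls,
    protein-interaction-network shortest-path spread statistics with random-sample
    envelopes, adjacency-restricted linkage-disequilibrium clustering of pQTL,
    phosphoproteome residual normalization, Richards growth-curve lag estimation,
    and a synthetic multi-omics cross generator with planted ground truth for
    end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    igraph,
    ranger,
    minpack.lm
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'coordination.R'
    'growth.R'
    'io.R'
    'network.R'
    'phospho.R'
    'pipeline.R'
    'pqtl_cluster.R'
    'qtl.R'
    'signature.R'
    'simulate.R'
    'stateQTL-package.R'
    'state_association.R'
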
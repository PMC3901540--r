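Package: realmod
Title: Realized Modularity and Null-Model Significance for Interaction Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A-posteriori assessment of how modular a network partition
    really is. Computes the realized modularity (the fraction of
    interactions established within modules, and its rescaled form on
    [-1, 1]) for any network/partition pair regardless of the method that
    produced the partition, alongside Newman-Girvan modularity. Includes a
    reference Louvain community detector, a degree-profile-preserving
    Bernoulli null model for directed networks (food webs, host-parasite
    systems), null-ensemble significance summaries with percentile
    confidence intervals, planted-partition and fixture generators, and a
    command-line front end. Networks are read from plain-text edge lists;
    bipartite incidence matrices are converted to directed unipartite
    networks before analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    optparse,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
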
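Package: hsmnet
Title: Hierarchy Inference in Directed Networks by Hierarchy Score Maximization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Infers, quantifies and statistically tests the hierarchical
    organisation of directed networks such as transcription-factor regulomes
    and kinase-substrate phosphorylomes. Nodes are arranged into L levels by
    simulated-annealing maximisation of a hierarchy score (the ratio of
    downward-plus-horizontal to upward-plus-horizontal edges); repeated runs
    are aggregated into a per-node level-probability matrix from which a
    probabilistic hierarchy score is computed. A corrected hierarchy score
    makes networks with different level counts comparable, and significance
    is assessed against Erdos-Renyi null networks. Also provides classical
    asymmetry metrics (dyadic reciprocity, Krackhardt hierarchy score,
    global reaching centrality), level-wise enrichment statistics,
    feed-forward-loop motif classification by level, and generators for
    planted-hierarchy and random benchmark networks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
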
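Package: HetNetProx
Title: Link Prediction and Candidate Gene Prioritization on Weighted
    Heterogeneous Biological Networks
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Data model and methods for typed, weighted heterogeneous
    biological graphs in which nodes are entities such as genes, proteins,
    pathways or articles and edges carry a relationship type and a
    reliability. Edge probabilities combine a per-type relevance
    coefficient, a degree-based informativeness penalty and the source
    reliability. Four node-proximity measures are provided (probability of
    best path, two-terminal network reliability, expected reliable
    distance, and a symmetric random walk with restart), together with a
    link-prediction evaluation harness (ROC/AUC, paired AUC comparison,
    negative-pair sampling, one-at-a-time relevance tuning) and three
    candidate-gene prioritization classifiers including a single-cluster
    selection method based on greedy edge-weighted clique search. A
    synthetic-graph generator with planted future links and planted gene
    families makes the full stack testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    igraph,
    Matrix,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
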
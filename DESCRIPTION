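Package: kgmoa
Title: Drug Repurposing and Mechanism-of-Action Path Prediction on
    Biomedical Knowledge Graphs
Version: 0.1.0
Authors@R:
    person("KG", "Maintainers", email = "maintainers@kgmoa.org",
           role = c("aut", "cre"))
Description: Tools for knowledge-graph based computational drug repurposing
    with mechanistic explanations.  Builds and customizes directed biomedical
    knowledge graphs, filters literature-derived drug-disease pairs with the
    publication-based normalized Google distance, learns neighborhood-aware
    node embeddings with a random-walk negative-sampling objective, trains a
    three-class (treat / not-treat / unknown) random-forest pair classifier,
    extracts target-anchored demonstration paths, and trains an adversarial
    actor-critic reinforcement-learning agent that proposes ranked
    mechanism-of-action paths from drug to disease.  Includes a seeded
    synthetic knowledge-graph generator with planted treatment pairs,
    mechanism paths and publication co-occurrence so the whole pipeline is
    testable end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    igraph,
    jsonlite,
    Matrix,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
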
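Package: compclust
Title: Compositional Clustering Agents for Task Structure Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Nonparametric Bayesian agents for grid-world navigation tasks
    whose contexts carry separable reward (goal) and transition
    (action-to-movement mapping) structure. Implements Chinese restaurant
    process clustering of contexts with hypothesis-based inference, either
    jointly over reward and mapping functions or independently for each
    (compositional generalization), plus a flat non-clustering baseline and
    meta-agents that arbitrate between the two strategies via reward
    prediction evidence. Includes model-based planning by value iteration,
    the diabolical rooms problem with compounding exploration costs, and an
    information-theoretic sequence-prediction analysis of when independent
    or joint clustering generalizes better as a function of mutual
    information and observation noise.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
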
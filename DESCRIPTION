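Package: dyhm
Title: Dynamic Hierarchical Stochastic Block Models for Evolving Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Clusters network vertices into the leaves of a fixed-depth
    binary tree under a hierarchical stochastic block model, and lets the
    membership evolve smoothly across coupled network snapshots (time
    points, tissues, or any neighbor structure over snapshots). Inference
    is by time-constrained variational mean-field coordinate ascent with
    Beta-Bernoulli conjugate tree parameters; a collapsed
    Metropolis-Hastings sampler over hard assignments serves as an
    asymptotically exact reference on small problems. Includes seeded
    planted-partition generators for static and dynamic benchmarks, a
    shared-neighbor hypergeometric baseline, co-membership scoring,
    precision-recall/F1 evaluation, penalized-likelihood selection of the
    smoothness weight, and edge-list/activity-matrix tooling for building
    snapshot series from expression data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
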
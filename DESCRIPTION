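Package: trophicstab
Title: Food-Web Stability Metrics and Fishing-Scenario Comparison
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the structure and local stability of weighted
    directed food webs. Computes trophic levels by a linear solve, mean trophic
    level, omnivory, directed (weighted) modularity maximised by simulated
    annealing, and quasi-sign-stability from ensembles of randomly
    parameterised community (Jacobian) matrices. Provides curveball
    degree-preserving topology randomisation and column-sum-preserving diet
    weight shuffles to build null distributions, Anderson-Darling two-sample
    comparison with median-difference effect sizes, construction of a
    fishery-augmented scenario web (fishery consumer plus discard resource),
    and a niche-model generator of synthetic marine food webs so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    Matrix,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
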
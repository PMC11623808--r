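Package: ecograph
Title: Eco-Evolutionary Dynamics of Mutant Fixation on Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how network population structure shapes the
    fate of a mutant whose fitness arises from competition for externally
    supplied resources. Implements a discrete-time Moran Birth-death process
    on arbitrary undirected graphs with global frequency-dependent fitness
    derived from a two-resource consumer-resource model, exact absorbing
    Markov-chain solvers for symmetric structures (well-mixed, star,
    preferential-attachment stars, and tiny-graph brute force), closed-form
    approximations in the weak and strong ecological-selection regimes,
    empirical estimation of network amplification factors, a diffusible-
    resource extension on the graph Laplacian, and finders for the
    amplifier/suppressor role-reversal boundary for deleterious mutants.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    Matrix,
    Rcpp,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
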
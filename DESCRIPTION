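Package: seqtlboga
Title: Quantum Self-Adaptive TLBO-GA Wrapper Feature Selection with SVM
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Wrapper feature selection for binary biomedical classification
    that simultaneously selects a feature subset and tunes the penalty C and
    RBF width sigma of a support vector machine. The search engine is a
    quantum-encoded, self-adaptive Teaching-Learning-Based Optimization
    hybridized with a self-adaptive genetic algorithm (SeQTLBOGA), alongside
    baseline metaheuristics (GA, PSO, cuckoo search, differential evolution,
    grasshopper) run under an equal evaluation budget. Includes stratified
    k-fold wrapper fitness with an internal SMO kernel-SVM solver, loaders
    for the two Wisconsin breast-cancer CSV dialects, a synthetic-data
    generator with a known informative subset, and Friedman rank tests with
    Holm, Hochberg and Li post-hoc procedures for benchmark comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    Rcpp,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
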
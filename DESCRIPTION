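Package: mednetbench
Title: Benchmarking Time-Series Network Inference on Chemically Mediated
    Microbial Communities
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An in-silico benchmark for time-series-based inference of
    microbial interaction networks. Simulates microbial communities under
    mediator-explicit (chemical cross-feeding) and direct generalized
    Lotka-Volterra dynamics with an Euler-Maruyama scheme, derives directed
    ground-truth interaction networks from analytic Jacobians, searches for
    diverse coexisting communities with an evolutionary algorithm, runs five
    inference methods (Pearson, Spearman, local similarity analysis,
    convergent cross mapping, LIMITS sparse regression), and scores them
    against the ground truth with ROC-AUC and precision.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    withr,
    stats,
    utils,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
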
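Package: gibbscape
Title: Thermodynamic Feasibility and Gibbs Energy Landscapes of Metabolic Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stoichiometry-based exploration of the Gibbs energy landscape of
    metabolic networks at steady state. Given a stoichiometric matrix and a
    vector of reaction directions, constructs thermodynamically consistent
    chemical-potential vectors by MinOver relaxation seeded from biochemical
    priors (standard formation energies and metabolite concentration ranges),
    and certifies, locates and removes thermodynamically infeasible reaction
    loops via Farkas-type certificates backed by an exact linear-programming
    oracle. Includes penalty and Agmon-Motzkin relaxation solvers for
    comparison, a synthetic network generator with planted ground truth, and
    a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    pracma,
    quadprog,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
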
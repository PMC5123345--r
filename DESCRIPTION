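Package: dltrs
Title: Bayesian Inference of Lateral Gene Transfer Under the DLTRS Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits the DLTRS model of gene-family evolution inside a dated
    species tree: gene duplication, gene loss and lateral gene transfer as a
    birth-death-transfer process on a time-discretized species tree, a
    gamma-relaxed molecular clock for edge substitution rates, and standard
    substitution models for sequence evolution. Inference is by
    Metropolis-Hastings MCMC over gene trees, edge lengths and model rates,
    with Rao-Blackwellised post-hoc sampling and maximum a posteriori
    estimation of realizations (time-stamped event placements, including
    donor and recipient species lineages for each transfer). Includes a
    ground-truth-recording simulator of the generative process, topological
    and temporal distances between realizations, MCMC convergence
    diagnostics, and cross-family summarization of transfer highways.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ape,
    phangorn,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite
Config/testthat/edition: 3
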
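Package: deerdock
Title: C2-Symmetric Dimer Docking and Ensemble Refinement from PELDOR/DEER Data
Version: 0.1.0
Authors@R:
    person("deerdock", "maintainers", email = "deerdock@example.org",
           role = c("aut", "cre"))
Description: Tools to determine the architecture of C2-symmetric membrane
    protein dimers from pulsed EPR (PELDOR/DEER) distance measurements.
    Provides forward simulation of dipolar time traces from spin-label
    position ensembles, non-negative Tikhonov inversion of form factors
    into distance distributions, exhaustive rigid-body grid docking under
    a two-fold symmetry constraint with local refinement, maximum-entropy
    (BioEn-style) reweighting of spin-label rotamer ensembles against
    experimental traces, and a stochastic heterodimer-mixing model for
    transport activity of protomer mixtures. A synthetic-data module
    generates toy protomers, ground-truth dimers, noisy dipolar traces and
    uptake time courses so the full pipeline is testable offline.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
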
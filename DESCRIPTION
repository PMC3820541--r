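Package: phosphorelay
Title: Steady-State, Stochastic and Kinetic Analysis of Four-Layered Phosphorelays
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing four-layered phosphorelay signaling systems
    (HK -> REC -> Hpt -> RR) under mass-action kinetics. Enumerates the 32
    relay topologies arising from optional reverse-phosphotransfer and
    hydrolysis reactions, computes exact steady-state signal-response curves
    by layer-by-layer flux-balance elimination, classifies curves as
    hyperbolic or sigmoidal from the curvature of the response at zero
    signal, evaluates analytic necessary conditions for sigmoidality and
    Hill coefficients, surveys sampled parameter spaces, quantifies
    intrinsic noise via exact stationary analysis of the molecular-count
    Markov chain and Gillespie simulation, measures step-response switching
    times, and supports model variants (bifunctional histidine kinase,
    phosphotransfer complexes, protein turnover, auto-dephosphorylation).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
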
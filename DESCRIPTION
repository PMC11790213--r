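Package: elevclade
Title: Simulating and Detecting Drivers of Elevational Diversity Gradients
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Mechanistic, population-based simulation of an endemic clade
    radiating over a mountain-shaped lattice, together with likelihood tools
    for detecting elevation-dependent diversification on phylogenies.  A
    continuous-time Gillespie engine models range expansion (colonization),
    local extinction (extirpation) and speciation of populations on cone- or
    plateau-shaped landscapes with elevational bands that differ in area,
    temperature, species-level carrying capacity and per-population
    diversification rate, optionally with local adaptation of temperature
    preferences under stabilizing selection.  Summary metrics quantify the
    strength and direction of the elevational diversity gradient, cross-band
    dispersal provenance, proportional range occupancy and equilibrium in
    regional richness.  A companion state-dependent speciation-extinction
    (SSE) module discretizes species elevations into three bands, enumerates
    fifteen transition-by-diversification model structures, computes their
    likelihood on ultrametric trees by pruning with numerical integration
    along branches, and compares them with AIC weights.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    ape,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    Matrix,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
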
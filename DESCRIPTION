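Package: archevol
Title: Comparative Phylogenetics of Plant Branching Architecture
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the evolution of plant branching architecture
    on a time-calibrated phylogeny. Computes functional branching indexes
    (photosynthetic and exploration) from individual plant measurements,
    integrates them into a single index by principal component analysis, and
    segregates species into architectural classes by rank-sum break
    detection with a compact letter display. Measures phylogenetic signal
    (Pagel's lambda, Blomberg's K) accounting for intraspecific variation,
    fits bivariate phylogenetic regressions with measurement error in both
    variables, performs Mk-model ancestral character estimation with AICc
    model selection, and fits families of multi-state speciation-extinction
    (MuSSE) models by ODE integration. Seeded simulators for birth-death
    trees, discrete characters, state-dependent diversification, Brownian
    traits with replicate noise, and per-individual architectural
    measurements make every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    deSolve,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    Matrix,
    phytools,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
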
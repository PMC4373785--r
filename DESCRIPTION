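Package: limfba
Title: Constraint-Based Metabolic Flux Estimation with Linear Inverse Models
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for constraint-based analysis of metabolic reaction
    networks formulated as linear inverse models. Imports and exports
    SBML reconstructions, assembles sub-networks by pathway, reaction or
    gene query, and estimates steady-state fluxes by linear programming
    (flux balance analysis) with flux variability analysis to assess
    uniqueness. Quantifies the uncertainty of flux estimates by
    Metropolis-Hastings ("mirror") sampling of the feasible flux polytope
    under Gaussian measurement likelihoods, and predicts disease flux
    distributions from gene-expression fold changes with Lsei-FBA, a
    least-squares projection of expression-scaled reference fluxes onto
    the steady-state constraint set. Ships a curated core model of human
    brain energy metabolism (glycolysis, pentose phosphate pathway,
    citric acid cycle, malate-aspartate shuttle, GABA shunt and oxidative
    phosphorylation) together with published cerebral exchange-flux
    measurements, and a generator of synthetic gene-expression fold-change
    tables for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    xml2,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    quadprog
Config/testthat/edition: 3
RoxygenNote: 7.3.3
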
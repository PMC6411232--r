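Package: maxentcc
Title: Maximum-Entropy Metabolic Models of Continuous Cell Cultures
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Self-consistent steady-state modelling of heterogeneous cell
    populations in chemostat-like continuous cultures. Cells are distributed
    over a feasible metabolic flux polytope according to a maximum-entropy
    distribution tilted on the biomass synthesis rate; extracellular
    concentrations, dilution rate, cell density, byproduct toxicity and
    stability of the steady state are computed self-consistently. Includes an
    exactly solvable two-dimensional overflow-metabolism network, brute-force
    moment oracles (rejection sampling and quadrature), an Expectation
    Propagation approximation for genome-scale polytopes, lexicographic
    flux balance analysis with an enzyme-crowding constraint, network
    reduction, and sweep/phase-diagram tooling.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
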
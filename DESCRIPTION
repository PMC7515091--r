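Package: rxnpaths
Title: Reaction-Counts Chemical Master Equation and Path Probabilities
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Exact transient analysis of stochastic mass-action reaction
    networks through the reaction-counts chemical master equation (CME).
    The state records how many times each reaction has fired, so the
    truncated generator is strictly lower triangular under a shell-blocked
    ordering and admits exact solutions. The package enumerates the
    reachable reaction-count lattice in shells, solves the reaction-counts
    CME with a certified truncation tail, pushes probabilities forward to
    the classical species-counts CME (with a direct finite-state-projection
    solver as cross-check), decomposes reaction-count states into
    independent path chains with closed-form exponential-polynomial
    probabilities, computes gated/un-gated cascade upper bounds on path
    probabilities, and provides a seeded Gillespie stochastic simulation
    oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, Matrix, stats, utils, parallel, jsonlite, yaml
Suggests: testthat (>= 3.0.0), deSolve, knitr
Config/testthat/edition: 3
biocViews: Software, StatisticalMethod, StochasticSimulation
RoxygenNote: 7.3.3
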
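Package: twophasepop
Title: Two-Phase Size-Structured Population Dynamics with Delayed Births
Version: 1.0.0
Authors@R:
    person("Ada", "Kovacs", email = "ada.kovacs@example.org",
           role = c("aut", "cre"))
Description: Simulation and spectral analysis of a linear two-phase
    size-structured population model in which individuals switch between a
    reproductive and a nonreproductive stage and newborns enter over a
    continuum of sizes after a distributed gestation delay. Provides a
    positivity-preserving conservative upwind finite-volume solver with a
    delay history buffer, computation of the Malthusian parameter and the
    stable size distribution via bisection on the spectral radius of a
    characteristic operator, a dense discretized-generator cross-check,
    adjoint (reproductive-value) eigenfunctions with a conserved pairing,
    numerical diagnostics of asynchronous exponential growth, and the
    equal-growth-rate reduction to a classical one-phase model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
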
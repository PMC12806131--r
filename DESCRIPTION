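Package: telosim
Title: Continuous-Time Random Walk Modelling of Telomere Shortening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and analytics for a continuous-time random walk
    (CTRW) model of telomere attrition during cell division. Waiting times
    between divisions follow heavy-tailed power laws (with or without
    exponential tempering) and the per-division shortening length follows a
    compound Normal-plus-Poisson law. The package provides exact samplers,
    densities, Laplace transforms and survival functions for the waiting-time
    laws; renewal-process trajectory and ensemble simulation with an absorbing
    critical length; closed-form and empirical moments with diffusion-regime
    classification of the ensemble-averaged mean squared displacement;
    explicit Gruenwald-Letnikov solvers for the fractional Fokker-Planck
    equations of the shortening-length density; and occupation-time and
    first-passage-time statistics via Monte Carlo cross-checked against a
    backward Feynman-Kac solver with a tempered fractional substantial
    derivative.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'waiting.R'
    'jumps.R'
    'ctrw.R'
    'moments.R'
    'fpe.R'
    'feynman-kac.R'
    'io.R'
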
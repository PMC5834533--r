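Package: fhnring
Title: Simulation and Robust Adaptive Synchronization of a Ring of Four
    FitzHugh-Nagumo Neurons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models a ring of four non-identical FitzHugh-Nagumo neurons
    coupled through direction-dependent gap junctions, driven by a common
    sinusoidal stimulation current and perturbed by bounded disturbances.
    Provides the closed-loop adaptive synchronization controller that steers
    the three slave neurons to the master neuron using a linear-in-parameters
    factorization of the error dynamics, with both a nominal adaptation law
    (for the disturbance-free network) and a leakage-modified robust law
    (uniform ultimate boundedness under bounded disturbances). Includes an
    ODE integration front-end with piecewise controller activation, Lyapunov
    function diagnostics, ultimate-bound calculators, largest Lyapunov
    exponent estimators (two-trajectory Benettin and time-series divergence
    methods) for chaos verification, trajectory export, and a command-line
    interface with reproduction presets.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
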
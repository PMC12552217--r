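Package: hbneuron
Title: Resonance, Multistability and Energetics of the Huber-Braun
    Thermosensitive Neuron
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Simulation and nonlinear-dynamics analysis of the four-variable
    Huber-Braun conductance-based model of thermosensitive sensory neurons
    under constant and subthreshold sinusoidal current forcing.  Provides the
    model vector field with Q10 temperature scaling, fixed points and their
    linearization, a compiled fixed-step fourth-order Runge-Kutta integrator,
    spike detection and interspike-interval statistics, p:q frequency-locking
    and Devil's-staircase analysis with Farey-sequence utilities, forward and
    backward parameter continuation with state inheritance, basin-of-attraction
    maps with uncertainty-exponent fractal-dimension estimates, maximum
    Lyapunov exponents by the Benettin two-trajectory method, and metabolic
    energy-consumption measures for the equivalent electrical circuit.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
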
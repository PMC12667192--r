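Package: gaitadapt
Title: Predictive Split-Belt Treadmill Walking Simulations with Cerebellar
    Gait Adaptation
Version: 0.1.0
Authors@R:
    person("Split-Belt", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Planar neuromusculoskeletal forward-dynamics simulator for
    split-belt treadmill walking. A reflex-based spinal gait controller
    (phase state machine, delayed force/length feedback, trunk
    proportional-derivative balance control) drives a 9 degree-of-freedom
    sagittal model with seven Hill-type muscle-tendon units per leg and
    Hunt-Crossley foot-belt contact. A cerebellar forward-model layer
    adapts the swing-initiation timing of each leg by gradient descent on
    a step-velocity-asymmetry prediction error, producing feedforward
    step-length-asymmetry adaptation. Includes the tiered treadmill
    objective function, a CMA-ES optimization harness with a staged
    belt-speed ramp protocol, a stride-level analysis pipeline (step
    metrics, spatial/temporal decomposition, exponential adaptation fits,
    waveform comparison), and a fast surrogate stride-map generator for
    closed-loop testing of the adaptation dynamics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
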
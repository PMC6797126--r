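Package: tapetraj
Title: Tape-Based Algorithmic Differentiation and Radau Collocation for
    Trajectory Optimization of Movement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Trajectory optimization of articulated (musculoskeletal) movement
    via direct collocation with implicit dynamics. Provides a tape-based
    algorithmic-differentiation engine (operator-overloaded recording of
    expression graphs, forward and reverse derivative sweeps, exact Hessians
    by forward-over-reverse, straight-line source emission), Hill-type muscle
    contraction and Raasch activation dynamics, planar rigid-body inverse
    dynamics with smoothed compliant (Hunt-Crossley) foot-ground contact,
    polynomial muscle-tendon geometry fitting, third-order Radau IIA
    collocation transcription into sparse nonlinear programs, and a
    primal-dual interior-point solver with exact or limited-memory
    quasi-Newton Hessians. Ships perturbed-balance pendulum problems and a
    planar muscle-driven predictive walking problem, plus a benchmark harness
    comparing algorithmic versus finite-difference derivatives.
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
    graphics,
    grDevices,
    compiler
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse
Config/testthat/edition: 3
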
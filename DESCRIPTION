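Package: hoverfall
Title: Closed-Loop Optic-Flow Control Models of Hoverfly Free-Fall Recovery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis toolkit for optic-flow-based flight
    stabilization in freely falling hoverflies. Implements a lumped-parameter
    closed-loop flight model (halteres-mediated PI pitch-rate control, visual
    PD regulation of the forward optic flow, a second-order flapping-wing
    force block and a fifth-order passive pitch-down block), an improved
    variant with vertical-optic-flow force feedback and absolute-pitch
    control, randomized free-fall ensembles with crash and instability
    detection, maximum-likelihood grid estimation of the visual controller
    gains, trajectory differentiation and stereo-metrology computations, and
    a synthetic-cohort generator emulating high-speed stereo recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    jsonlite,
    yaml,
    minpack.lm,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    MASS,
    deSolve,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
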
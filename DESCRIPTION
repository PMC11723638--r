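Package: cupshaper
Title: Input Shaping and Internal-Model Fitting for Cart-Pendulum Object
    Transport
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and model-comparison toolkit for point-to-point
    transport of an underactuated cart-pendulum object (a "cup with a ball
    rolling inside") moved by a hand modelled as mechanical impedance plus a
    feedforward force.  Implements zero-vibration (ZV) and multi-mode
    convolved input shapers applied to minimum-jerk nominal profiles, five
    candidate internal models (multi-mode, slow-mode, fast-mode, rigid-body,
    no-impedance) that each produce a shaped command and feedforward force,
    fixed-step RK4 integration of the coupled linear and nonlinear
    hand-object dynamics, per-trial performance metrics (trimming, velocity
    peak ratio, inter-peak minimum velocity, residual ball angle, variance
    accounted for), per-trial impedance fitting by a controlled random
    search (CRS2 with local mutation) global optimizer, a synthetic-trial
    generator with human-like variability, and simplified regression and
    t-test summaries for cross-model comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    Matrix,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
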
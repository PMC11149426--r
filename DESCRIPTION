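Package: bioeye
Title: Six Degree-of-Freedom Biomimetic Eye: Tendon-Driven Plant, Optimal
    Saccade Control, and 3D Kinematics Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates a biomimetic robotic eye driven by six elastic
    tendons with human-like insertions, integrated as a Newton-Euler
    rigid body at 1 ms resolution. Saccades are generated by an optimal
    controller that trades off endpoint accuracy, movement duration and
    motor energy over a grid of candidate durations, optionally through a
    recurrent input-output surrogate of the plant identified from
    pseudo-random binary excitation. A full 3D analysis suite quantifies
    the resulting movements: Listing's plane fits, main-sequence
    dynamics, trajectory curvature, component cross-coupling,
    position-dependent velocity gains, muscle synergies, and simulated
    muscle-stimulation experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    nnet,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
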
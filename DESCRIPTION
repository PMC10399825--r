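Package: myoelbow
Title: EMG-Driven Biomechanical Simulation of the Human Elbow
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Predicts elbow joint movement from surface electromyography
    (sEMG) of the biceps and triceps brachii with a Hill-type musculoskeletal
    model. Raw sEMG is amplified, bandpass filtered and rectified into neural
    excitation, converted to muscle activation by first-order activation
    dynamics and an exponential recruitment nonlinearity, and turned into
    muscle force by force-length, force-velocity and passive-elastic
    submodels. Joint geometry maps forces to torques and a forward dynamics
    integrator produces the simulated elbow angle. Thirty-seven model
    parameters are derived from eight easily measured anthropometric
    quantities; the remaining five (four sEMG gains and a triceps length
    offset) are calibrated per trial by a seeded random-walk search followed
    by bounded trust-region least squares. Includes nMAE and quality-score
    evaluation metrics, a synthetic-trial generator for validation, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    deSolve,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
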
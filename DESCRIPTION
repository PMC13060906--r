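Package: reachmotif
Title: Motif Segmentation and Neural Analysis of Skilled Mouse Forelimb Reaching
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for the freely moving mouse water-reaching task:
    reconstruction of 3D forelimb kinematics from two orthogonal camera views,
    frame-wise segmentation of the reach into stereotyped motor motifs
    (Lift, Reach, Open, Grasp, Retract, Drink) with a gated recurrent unit
    classifier, the full motif/trial/session kinematic metric suite,
    isosbestic-corrected fiber-photometry analysis, single-cell calcium
    modulation tests and linear population decoding of 3D kinematics, and
    peri-event analysis of optogenetic perturbation trials with pseudo-laser
    controls. A semi-Markov synthetic-session generator with known ground
    truth (labels, templates, encoding weights, perturbation effects) makes
    every stage testable without raw recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
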
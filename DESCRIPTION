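Package: dodgegaze
Title: Simulated Obstacle-Dodging Gameplay and Gaze-Based Analysis of Sense of Control
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A frame-accurate simulator of a vertically scrolling
    obstacle-avoidance task with stochastic motor perturbations (input noise
    and lateral drift), scripted agents that play it, a generator of synthetic
    binocular 2000-Hz gaze streams aligned to gameplay, velocity- and
    displacement-based fixation and saccade detection, a one-dimensional
    k-quantiles split of fixations into Close and Distant classes by distance
    to the controlled sprite, per-fixation distance measures, and the
    downstream inference stage: Box-Cox transform selection, (generalized)
    linear mixed models with BIC-selected random-effects structures,
    successive-difference contrasts, a |z| >= 2 significance criterion, and
    parametric-bootstrap highest-density confidence intervals. Designed for
    parameter-recovery studies of gaze-based sense-of-control analyses on
    fully synthetic cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    lme4,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
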
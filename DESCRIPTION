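Package: adcascade
Title: Personalized Alzheimer's Biomarker-Cascade Modeling and Optimal
    Anti-Amyloid Therapy Planning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for personalized modeling of Alzheimer's disease
    progression and in-silico treatment planning. Implements a five-state
    ordinary-differential-equation cascade linking amyloid-beta, phosphorylated
    tau, age-related (non-amyloid) tauopathy, neurodegeneration and cognitive
    impairment; a sequential equation-by-equation nonlinear least-squares
    calibration of all subject-level parameters from longitudinal biomarker
    series, followed by joint refinement; and a Pontryagin maximum-principle
    optimal-control solver (forward-backward sweep on a shared fixed
    Runge-Kutta grid) for anti-amyloid-beta therapy with an amyloid- and
    time-dependent side-effect penalty. Includes calibration of maximum drug
    clearance rates from published trial amyloid-reduction outcomes
    (aducanumab low/high dose, donanemab), a synthetic longitudinal cohort
    generator with known ground truth for validation, and an in-silico
    clinical-trial runner reporting cognitive-percentage-change tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    deSolve,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
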
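Package: gaitstab
Title: Margins of Stability and Perturbation Responses for Treadmill Gait
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying gait stability from 3D marker kinematics
    recorded during dual-belt treadmill walking. Implements zero-phase
    Butterworth filtering of marker data, heel-strike detection from the
    anterior-posterior heel-to-pelvis excursion, spatio-temporal step
    parameters, extrapolated centre-of-mass (XCoM) margins of stability in
    the medio-lateral and anterior-posterior directions, the 6S summary of
    deviation from baseline walking over six post-perturbation steps, and
    local dynamic stability (maximum divergence exponent) of trunk velocity.
    A synthetic treadmill-walking generator reproduces six perturbation
    types (ipsi- and contralateral platform sway, unilateral belt
    acceleration and deceleration, visual and auditory) with ground-truth
    step parameters, so the full pipeline can be exercised and validated
    without motion-capture data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    Rcpp,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
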
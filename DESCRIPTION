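Package: neckdyn
Title: Multibody Cervical Spine Dynamics and Impact-Specific Bushing
    Parameter Identification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Forward dynamics of a C2-C6 cervical spine modelled as a rigid-body
    chain coupled by six degree-of-freedom Kelvin-Voigt bushing joints, and
    identification of impact-specific axial and shear viscoelastic parameters
    (stiffness and damping) from high-speed marker trajectories recorded during
    impulsive axial loading. Provides zero-phase Butterworth preprocessing of
    force and marker signals, impact-onset detection and windowing, a genetic
    algorithm that minimises marker-tracking root-mean-square error, five-fold
    cross-validation of transferred median parameters, Monte Carlo and
    joint-frame-position sensitivity analyses with cubic response surfaces, a
    head-impact scenario comparison of model variants, and a synthetic-specimen
    generator with known ground truth for end-to-end verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils,
    graphics,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
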
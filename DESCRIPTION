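Package: rv2g
Title: Two-Zero-Load-Geometry Right Ventricle Mechanics and Outcome Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale toolkit for patient-specific right-ventricle mechanics
    with separate zero-load diastole and systole reference geometries.
    Provides anisotropic Mooney-Rivlin and Fung-type hyperelastic constitutive
    laws with stress evaluation and parameter fitting, recovery of zero-load
    geometries from in-vivo contour stacks by an iterative pre-shrink,
    quasi-static thick-walled chamber inflation with a two-phase cardiac-cycle
    simulator, geometric quantification of short-axis contour stacks
    (Simpson-method volumes, wall thickness, circumferential and longitudinal
    curvature), cohort statistics (t-tests, Pearson correlation, random-intercept
    mixed models), and repeated cross-validated logistic regression for
    post-pulmonary-valve-replacement outcome prediction, together with a
    published 16-patient cohort as machine-readable fixtures and synthetic
    geometry and cohort generators.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    lme4
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
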
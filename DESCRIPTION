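Package: lemr
Title: Latent Ergonomics Maps for Whole-Body Posture Assessment
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Ergonomic assessment of whole-body human postures for
    occupational-risk analysis. Builds an anthropometric rigid multi-body
    digital human model (66 revolute degrees of freedom on a 6-DoF floating
    base), estimates joint torques by floating-base inverse dynamics with a
    body-weight foot-wrench approximation, scores postures with the Rapid
    Upper Limb Assessment (RULA) worksheet and with a continuous relaxation
    (RULA-C) obtained from per-joint quadratic fits and regression-fitted
    table combinations, learns a two-dimensional latent posture space with a
    relational variational auto-encoder, and renders ergonomics scores as
    color-coded latent height-maps onto which recorded motions are projected
    as traces. Includes a keyframe-based synthetic motion generator and a
    Cartesian impedance wrench source for end-to-end experimentation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    png,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
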
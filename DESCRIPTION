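Package: bowlruler
Title: Single-Image Geometric Measurement of Circular Dining Bowls
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Models a circular dining bowl as a power-law surface of
    revolution and recovers its rim radius, height, shape exponent and
    volume from a single photograph of an adhesive paper ruler taped
    across the bowl interior. Provides the parametric bowl model with
    closed-form volume and plumpness, a pinhole-camera simulator that
    places a virtual ruler on the bowl and projects its edge landmarks,
    a coarse-to-fine reprojection-error estimator with
    Levenberg-Marquardt camera-pose fitting, first-order propagation of
    parameter errors into volumetric error, preprocessing of
    hand-labeled ruler landmarks, and validation of the surface model
    against scanned 3D point clouds.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
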
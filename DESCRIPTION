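Package: vaangle
Title: Vascular Arcades Angle Measurement from Fundus Photographs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated measurement of the fundus vascular arcades angle (VAA)
    at one and two papillary diameters from the optic-disc centre on colour
    fundus photographs: region-of-interest extraction and enhancement, optic
    disc segmentation by polar-transform edge detection with a minimum
    enclosing circle, multiscale vessel segmentation and arcade tracing,
    quadratic Bezier fitting of the arcades and circle-curve intersection to
    obtain the angles. Ships a synthetic fundus-scene generator with analytic
    ground truth and a synthetic two-visit cohort generator, plus the
    cohort-level statistics linking VAA and its longitudinal change to
    choroidal thickness (paired change tests, adjusted regression, trend
    across VAA groups, multivariable change models with collinearity
    screening) and the automated-versus-manual validation metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    car,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
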
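Package: stomech
Title: Guard-Cell Wall Mechanics and AFM Stiffness Mapping of Stomata
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying the mechanics of stomatal guard cells. Builds
    a parametric finite-element surface mesh of a pressurized guard-cell pair,
    models the wall as a transversely isotropic Veronda-Westmann hyperelastic
    membrane with circumferential cellulose microfibrils, and solves the
    quasi-static inflation problem under staged turgor and epidermal pressure
    to predict aperture-pressure response curves, complex-length changes and
    wall strain/stress fields for baseline, variable-wall-thickness and
    fixed-pole model variants. Also implements an atomic-force-microscopy
    force-volume pipeline (calibration, baseline/tilt correction, contact-point
    detection, pyramidal Hertz fitting) that turns grids of force-distance
    curves into apparent-modulus maps, stomatal transect profiles and a
    radial stiffness-gradient statistic, together with a synthetic force-map
    generator with known ground truth for validating the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    minpack.lm,
    pracma,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
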
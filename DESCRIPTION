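Package: aortassr
Title: Synthetic Aortic Haemodynamics, Wall Shear Stress Decomposition and
    the Shear Stress Ratio
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale pipeline for thoracic-aorta haemodynamic modelling and
    marker extraction. Builds parametric vessel geometries with
    rotation-minimizing centerline frames, generates analytic pulsatile
    velocity fields with controllable jet eccentricity and helical secondary
    flow (including phase-contrast MRI-like degraded copies), propagates
    pulse waves through a 1D elastic-tube surrogate with two-element
    Windkessel outlets, calibrates wall stiffness to a target pulse wave
    velocity through the Moens-Korteweg relation and tunes outlet resistance
    to a target flow split, and extracts flow displacement, jet angle,
    maximum velocity, axial/circumferential wall shear stress and the
    dimensionless shear stress ratio (SSR), with regional quadrant/segment
    statistics, cumulative-frequency summaries and non-parametric group
    comparison for cohort stratification experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
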
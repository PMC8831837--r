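Package: vesselrt
Title: Radon-Transform Measurement of Retinal Vessel Width and Angle
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Measures the geometry of the major temporal retinal vessels in
    fundus photographs of preterm infants screened for retinopathy of
    prematurity (ROP). A Radon-transform line detector tracks each vessel
    centerline from a manual seed to a distal target, vessel caliber is
    estimated from parallel line integrals and edge localization, and the
    temporal artery/vein angle is obtained by intersecting straight-line
    fits to the superior and inferior arms. Includes a synthetic fundus
    phantom generator with known ground truth, cohort simulation from
    per-stage summary statistics, and the accompanying statistics (one-way
    ANOVA from raw data or summary rows, Tukey-Kramer multiple comparisons,
    Pearson correlation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    tiff,
    MASS,
    stats,
    utils
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
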
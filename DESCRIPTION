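Package: syndrs
Title: Diffuse Reflectance Spectroscopy of Synovial Fluid
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for noncontact diffuse reflectance spectroscopy (DRS) of synovial
    fluid samples held in syringes. Implements Mie theory for designing polystyrene
    microsphere phantoms, oxyhemoglobin absorption bookkeeping, a diffusion-dipole
    forward model of spatially resolved reflectance at a fixed source-detector
    separation, a calibration pipeline turning raw triplicate shots into calibrated
    reflectance and two-wavelength ratio biomarkers (R490/R600 and R580/R600), a
    synthetic patient-cohort simulator (white and red blood cell counts, saline
    dilution, infection labels), and exact nonparametric statistics (Mann-Whitney U
    by network enumeration, Spearman correlation by permutation) for small-cohort
    group comparisons and biomarker-laboratory correlations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
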
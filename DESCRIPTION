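Package: cornoct
Title: Corneal Sublayer Segmentation and Repeatability Statistics for
    Ultra-High-Resolution OCT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulates ultra-high-resolution anterior-segment OCT B-scans of
    the human cornea before and after thin-flap refractive surgery
    (sub-Bowman's keratomileusis), automatically segments the air-epithelium,
    epithelium-Bowman's, Bowman's-stroma, flap and endothelium-aqueous
    interfaces from longitudinal reflectivity profiles, converts optical
    interface separations to geometric sublayer thicknesses, and computes
    intrasession repeatability statistics (intraclass correlation,
    coefficient of repeatability, Bland-Altman limits of agreement) together
    with longitudinal change and between-group comparison statistics for
    cohort studies of corneal pachymetry.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tiff,
    png,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
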
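Package: axonmetry
Title: Single-Axon White-Matter Morphometry from 2D Micrographs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Morphometric analysis of myelinated axons in white-matter
    cross-sections: profile segmentation and measurement (diameters, myelin
    thickness, g-ratio, aspect ratio, orientation), areal-fraction density,
    four-way axon size classification by exact one-dimensional k-means,
    orientation-anisotropy statistics (aspect-ratio-filtered, peak-aligned
    angle dispersion with elongated-fraction weighting), design-based
    stereological cell-density estimation with the optical fractionator and
    coefficient-of-error reporting, and developmental-trajectory statistics
    (group ANOVA and group-by-age ANCOVA). A synthetic-tissue generator
    produces ground-truth 3D axon populations, rendered cross-section
    micrographs, simulated developmental cohorts and 3D cell populations so
    that every stage of the pipeline is verifiable against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    png,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
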
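Package: icethick
Title: Ice-Thickness Mapping and Thickness-Based Hole Targeting for Cryo-EM
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Determines vitreous ice thickness in single-particle cryo-EM
    from low-magnification grid-square images, using either the zero-loss
    energy-filter method (log ratio of unfiltered to filtered intensity,
    scaled by an apparent inelastic mean free path) or the aperture-limited
    scattering method (log ratio of a vacuum reference to the observed
    intensity). Provides calibration of the scaling constants and the
    empty-hole correction term, per-pixel thickness maps with heatmap
    rendering, detection of the hole lattice in holey support films,
    per-hole thickness measurement, threshold-based target selection,
    grouping of targets into beam-image-shift acquisition patterns, and
    export of SerialEM Navigator-style target lists. A synthetic
    grid-square simulator with known ground truth makes the whole
    workflow testable without microscope data.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    png
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
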
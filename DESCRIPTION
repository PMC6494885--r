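Package: slicetrack
Title: Longitudinal 4D Single-Cell Tracking and Survival Analysis for
    Organotypic Slice Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Automated analysis of long-term 4D (x, y, z, time) fluorescence
    imaging of organotypic brain slice cultures: calibrated 5-D image series
    I/O with maximum z-projection, tile stitching and translation alignment;
    normalised-threshold segmentation of single cells; proximity-based
    longitudinal tracking with a hard distance cutoff; per-cell morphology,
    motility and intensity-trend quantification; inclusion-body puncta
    detection and size classification inside neuron masks; and single-cell
    survival statistics (Kaplan-Meier, Gehan-Breslow-Wilcoxon, Cox
    proportional hazards, hazard-linearity testing). A seeded synthetic-movie
    simulator with full ground truth makes every stage verifiable without
    microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    survival,
    tiff,
    xml2,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
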
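Package: hdgcellkit
Title: Multiclass Tumor Cell Detection Toolkit for Hereditary Diffuse Gastric Cancer Histopathology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Model-agnostic tools for point-annotation based tumor cell
    detection in hereditary diffuse gastric cancer (HDGC) histopathology.
    Converts point annotations of typical signet ring cells, atypical signet
    ring cells and non-signet-ring tumor cells into body/membrane segmentation
    rasters and back into point detections; scores detections against
    reference annotations under a micrometer hit-radius criterion (per-class
    and overall F1, lesion-level count agreement and Jensen-Shannon
    distribution similarity); provides reader-study agreement statistics
    (pairwise matrices, t and bootstrap confidence intervals, Wilcoxon tests,
    agreement heatmaps); implements weighted patch sampling and hard-negative
    mining for two-stage detector training; and ships synthetic slide,
    probability-raster and noisy-reader simulators so the full pipeline runs
    without any whole-slide image.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    xml2,
    jsonlite,
    yaml,
    png,
    tiff,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
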
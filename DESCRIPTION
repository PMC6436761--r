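Package: yeastseg
Title: Automated Seeding, Segmentation and Backwards Tracking of Budding
    Yeast Time-Lapse Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Marker-free segmentation and tracking of budding yeast colonies
    in 2-D grayscale time-lapse microscopy (phase contrast, bright-field, or
    phase/fluorescence composites). The last frame is seeded fully
    automatically by a watershed over a contour-derived topography, followed
    by threshold-voting correction of under-segmentation, iterative
    score-based boundary fine-tuning, overlap-based merging of
    over-segmented fragments, and score-weighted distribution of disputed
    pixels. Cells are then followed backwards in time until they are born,
    so buds never have to be detected de novo. Includes the quantitative
    evaluation metrics (F-measure, error classes, area-gain and periphery
    quantification), robustness experiment harnesses, and a seeded synthetic
    colony generator with ground truth for benchmarking.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    tiff,
    yaml,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
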
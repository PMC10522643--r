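Package: glowlabel
Title: Fluorescence-Derived Landmark Labels for Markerless Pose Tracking
Version: 0.1.0
Authors@R: person("glowlabel", "developers", email = "glowlabel@example.org",
    role = c("aut", "cre"))
Description: Tools for synthesizing landmark training labels from hidden
    fluorescent fiducials. Models strobed UV/visible illumination schedules and
    frame pairing, extracts dye-blob centroid labels (threshold, morphological
    cleaning, centroid, first-class absent handling), detects and matches
    speckle "visual barcode" keypoints with spatial-coherency filtering, ranks
    template images by greedy feature coverage, propagates labels by median
    pooling or local homographies, builds stride-downsampled training targets
    with interleaved loss masks, and evaluates detector predictions (pixel
    error, on-target precision-recall, AUC) with confidence-driven test-time
    scale optimization. All stages are exercised on seeded synthetic imagery;
    no real recordings are required.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    png,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
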
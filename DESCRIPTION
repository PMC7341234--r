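Package: activityindex
Title: Broiler Activity Index from Top-View Image Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the frame-differencing activity index (AI) used in
    precision livestock farming to quantify broiler movement from top-view
    video. Implements threshold calibration from empty-background frames,
    binary inter-frame motion masks, bird-pixel segmentation and
    normalisation, temporal subsampling of frame sequences at arbitrary
    intervals, cumulative activity over fixed time windows, ratio-to-baseline
    comparisons across sampling intervals, and grouped mean/SEM summaries.
    Ships a seeded synthetic flock simulator (moving bird-shaped blobs on
    textured litter with sensor noise, resting bouts and sub-second transient
    movements) with exact ground truth, so the whole pipeline is testable
    without video data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    dplyr,
    png,
    readr,
    rlang,
    stats,
    tibble,
    tiff,
    tools,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
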
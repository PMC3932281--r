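Package: mmtdfcm
Title: Noise-Robust Fuzzy C-Means Image Segmentation with Medium
    Truth Degree Spatial Weighting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segments single-channel 8-bit grayscale images (for example
    magnetic resonance slices) by fuzzy c-means clustering of gray levels,
    with a spatially regularized variant (MMTDFCM) that blends each pixel's
    fuzzy membership with the mean membership of its 3x3 neighborhood.  The
    blend weight is a per-pixel medium-truth-degree similarity score between
    the pixel and its eight neighbors, so homogeneous regions are smoothed
    while pixels unlike their surroundings retain their own membership.
    Includes the classical fuzzy c-means baseline, cluster validity indices
    (partition coefficient and partition entropy), peak signal-to-noise
    ratio, synthetic phantom images with salt-and-pepper and Gaussian noise
    models, PNG/TIFF input and output, and a command-line driver for paired
    algorithm comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    png,
    tiff,
    yaml,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
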
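Package: litchigrade
Title: Hyperspectral Micro-Damage Grading of Litchi Fruit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for grading post-harvest litchi fruit by pericarp
    micro-damage from 400-1000 nm visible/near-infrared hyperspectral
    images. Implements white/dark reference reflectance calibration of
    ENVI-style cubes, region-of-interest mean-spectrum extraction with
    Savitzky-Golay smoothing, baseline correction and detrending,
    PLS-DA discrimination of four quality classes (fresh, newly damaged,
    2 h and 4 h after damage), characteristic-waveband selection from
    principal-component loading extrema, bruise segmentation by histogram
    equalization, Otsu thresholding, Roberts edge detection and fuzzy
    c-means clustering, gray-level co-occurrence matrix texture
    descriptors, and least-squares support-vector-machine classification.
    A seeded synthetic-scene generator produces litchi-like cubes with
    ground-truth masks so the full pipeline can be exercised and validated
    at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    rlang,
    ggplot2,
    signal,
    jsonlite,
    yaml,
    generics
Suggests:
    testthat (>= 3.0.0),
    withr,
    e1071,
    png
Config/testthat/edition: 3
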
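Package: sproutquant
Title: Quantification of Microvascular Sprouting Area in Explant Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures the area covered by microvascular sprouts radiating from
    cultured tissue explants (e.g. choroid or aortic explants) in single-channel
    phase-contrast images. The explant body is segmented by deterministic seeded
    region growing (a reproducible "magic wand"), removed from the image, and the
    sprouts are isolated by intensity thresholding with optional region-of-interest
    background exclusion; areas are reported in pixels and in calibrated mm^2.
    Includes within-batch normalization to control, the summary statistics used in
    sprouting assays (mean +/- SEM, unpaired t-test, one- and two-way ANOVA with
    Bonferroni post-hoc), a batch pipeline driven by a CSV manifest, and a
    synthetic explant-image generator with pixel-exact ground truth for
    validation and power exploration of dose-response designs.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    car,
    grDevices,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    EBImage,
    mgcv,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
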
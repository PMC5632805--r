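Package: phenowell
Title: High-Throughput Multi-Well Plate Phenotyping of Rosette Growth
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated analysis of top-view RGB images of Arabidopsis seedlings
    grown in 6-, 12- and 24-well plates: radial lens-distortion correction,
    fiducial-based plate registration with ranked candidate transforms and a
    validation/retry loop, HSV colour segmentation, and per-well green-area
    extraction. Downstream statistics cover exponential growth fits, relative
    growth rates, survival, population quartile summaries, and Kruskal-Wallis
    group comparison with Conover post-hoc tests and compact letter displays.
    Includes a ground-truthed synthetic plate and growth-experiment generator
    so the whole pipeline can be benchmarked without platform hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    png,
    yaml,
    grDevices,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
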
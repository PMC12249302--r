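Package: sishdetect
Title: Star-Convex Nuclei Detection for HER2-SISH Brightfield Histology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-stage nuclei detection for silver-enhanced in situ
    hybridization (SISH) breast-tissue images. Provides Macenko stain
    normalization in optical-density space, global/local foreground
    extraction, a star-convex polygon geometry engine (radial distance
    ground truth, polygon IoU, greedy non-maximum suppression), a compact
    trainable U-Net predictor of object probability and radial boundary
    distances, watershed-bootstrapped pseudo-labeling, an object-level
    TP/FP/FN evaluation protocol with expert-criteria filtering, and a
    seeded synthetic SISH scene generator with full ground truth so the
    entire pipeline runs and is validated without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    withr
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
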
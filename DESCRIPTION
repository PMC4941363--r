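Package: hcskit
Title: High-Content Screening Image Analysis with a Ground-Truth Simulator
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Single-cell high-content microscopy analysis for nuclear-receptor
    screens: nuclear segmentation (rolling-ball background subtraction,
    locally adaptive mean thresholding, distance-transform seeded watershed),
    approximate cell masks by contested dilation, per-cell receptor level and
    nuclear/cytoplasmic translocation measurements, EdU S-phase
    classification, mitochondria morphometry and JC-1 red/green ratios,
    plate-control normalization, four-parameter logistic dose-response (IC50)
    fitting, hierarchical clustering of compound-by-cell-line response
    profiles, and Biolog phenotype-microarray Z-scoring. Ships a synthetic
    multi-channel plate simulator with per-cell ground truth so every stage
    has a known-answer test bed.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    minpack.lm,
    tiff,
    ape
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
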
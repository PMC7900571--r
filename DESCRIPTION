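Package: carthick
Title: Knee Cartilage Thickness Quantification and Cohort Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies articular cartilage thickness of the knee from
    bone and cartilage segmentation label volumes using signed Euclidean
    distance maps, gradient dot-product boundary classification, and an
    outer-boundary distance map; partitions cartilage into the 14 WORMS
    anatomical regions with a geometric atlas and a pluggable alignment
    transform; evaluates segmentations with the Dice similarity
    coefficient; and runs the cohort statistics (Tukey simultaneous
    pairwise comparisons, age-by-condition interaction regressions with
    confidence bands). Includes a synthetic-data module that generates
    knee phantoms with analytically known thickness and cohorts with a
    configurable covariate structure, plus minimal NIfTI-1 input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite,
    truncnorm
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
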
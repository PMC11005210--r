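Package: oedgrader
Title: Detection and Grading of Oral Epithelial Dysplasia from Tiled Slide Images
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A testable re-implementation of a computational-pathology
    pipeline for grading oral epithelial dysplasia (OED) in oral
    leukoplakia slides. Slide images are split into non-overlapping
    patches, background patches are filtered by a brightness rule,
    twelve dysplasia features are scored per patch by pluggable binary
    classifiers, scores are averaged to the slide level, and slides are
    graded (hyperplasia, mild, moderate, severe) with a cumulative-logit
    (proportional-odds) ordinal fusion model. Includes patch-majority
    grading, heatmap rendering, macro-averaged multiclass evaluation
    with bootstrap confidence intervals, and a synthetic-slide generator
    with known ground truth so every stage is testable without
    clinical images.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports: methods, stats, utils, png, jsonlite, yaml
Suggests: testthat (>= 3.0.0), withr, MASS, pROC, tiff, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Classification, Regression, Software
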
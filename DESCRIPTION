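Package: lidecon
Title: Deconstructed Laterality Indices for fMRI Language Lateralisation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes threshold-dependent laterality indices (LI) from
    voxel-wise statistic maps and deconstructs the LI into separate measures
    of laterality (L-R) and activation strength (L+R). Builds data-driven
    nested region-of-interest ladders from labelled cohorts by percentile
    thresholding of left-right difference t-maps, classifies cases as left,
    bilateral, right or inconclusive with an ensemble of probabilistic linear
    classifiers fitted at above-chance (threshold, ROI-size) parameter
    combinations, scores and categorises Wada test results for validation,
    and generates synthetic t-map cohorts with known ground-truth laterality
    so every stage can be tested without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    RNifti,
    MASS,
    nnet,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
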
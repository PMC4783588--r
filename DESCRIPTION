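Package: rdmfit
Title: Weighted Representational Modeling of Dissimilarity Matrices by
    Non-Negative Least Squares
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for representational similarity analysis in which a data
    representational dissimilarity matrix (RDM) -- from multivoxel fMRI
    activity patterns or from behavioral similarity judgments -- is explained
    as a non-negatively weighted sum of single-dimension model RDMs derived
    from binary category and feature dimensions. Provides RDM construction
    (correlation distance), dimension-model building from human labeling
    votes (generation and validation thresholds, correlated-dimension
    merging), iterative aggregation of multi-arrangement similarity trials,
    cross-validated non-negative least-squares fitting with a confound-mean
    predictor, Kendall tau-a model evaluation with stimulus-label
    randomization tests, stimulus-bootstrap model comparisons, false
    discovery rate control, noise ceilings, second-order RDM embedding by
    metric-stress multidimensional scaling, and a synthetic-data generator
    with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
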
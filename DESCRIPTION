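Package: trfusion
Title: Time-Resolved Representational Similarity Analysis and EEG-fMRI Fusion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the spatiotemporal dynamics of visual and
    social-affective processing with multivariate electroencephalography (EEG)
    pattern analysis. Implements time-resolved pairwise decoding of stimulus
    conditions into representational dissimilarity matrices (RDMs), model RDM
    construction from stimulus features (convolutional-layer activations,
    motion energy, category labels, ratings, pairwise similarity judgments)
    and from fMRI region-of-interest multivoxel patterns, rank-correlation and
    multiple-regression representational similarity analysis with
    leave-one-subject-out noise ceilings, onset-latency estimation and
    comparison, variance partitioning (commonality analysis) of EEG pattern
    variance across up to three predictors, and group-level one-tailed
    sign-permutation tests with maximum-cluster-sum correction. A synthetic
    EEG and ROI-RDM generator with known representational geometry, onset
    latencies, and variance decomposition provides ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    signal,
    stats,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
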
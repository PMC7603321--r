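Package: wmtopo
Title: Small-World Topology of White-Matter Functional Connectomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Builds and analyzes white-matter functional connectomes from
    voxel time series or precomputed per-subject connectivity matrices.
    Provides random region-growing parcellation of a binary voxel mask into
    contiguous, size-balanced nodes, Fisher-z functional connectivity,
    proportional sparsity thresholding, weighted small-world metrics
    (normalized clustering, normalized path length, small-worldness) against
    degree-preserving null networks with area-under-curve summarization over
    a sparsity sweep, covariate-adjusted group comparisons, symptom
    correlations, support-vector regression severity prediction with
    cross-validation, and balanced-subsample ensemble support-vector-machine
    classification. A synthetic-cohort generator with planted group and
    symptom effects makes the full analysis chain runnable and testable
    without external imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
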
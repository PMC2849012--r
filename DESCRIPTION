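Package: episearch
Title: Searchlight Decoding of Episodic Memory Patterns with Group Overlap Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested pipeline for multivoxel pattern analysis of episodic
    memory fMRI experiments: synthetic 4D BOLD simulation with implanted
    class-specific multivoxel signal, linear detrending and hemodynamic onset
    shifting, trial-pattern extraction from ROI masks, searchlight-based
    multivariate feature selection, multiclass linear support-vector-machine
    decoding under nested leave-one-trial-out cross-validation, permutation
    estimates of chance, per-subject information maps, and group-level
    frequency heat maps tested voxelwise against the binomial distribution.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    tools,
    utils,
    tibble,
    dplyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    readr,
    RNifti,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    e1071,
    withr
Config/testthat/edition: 3
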
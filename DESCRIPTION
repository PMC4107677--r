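Package: stnfc
Title: Seed-Based Resting-State Functional Connectivity Aging Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for age-related differences in seed-based
    resting-state functional connectivity of the subthalamic nucleus (STN).
    Takes per-subject 4D BOLD volumes, motion-parameter tables, a label
    atlas marking bilateral seed regions and tissue classes, and a
    multi-site phenotype table; performs nuisance regression and band-pass
    filtering, extracts first-eigenvariate seed time series, computes
    voxel-wise Fisher-Z connectivity maps, fits a covariate-adjusted group
    model with conjunction contrasts, controls cluster-level family-wise
    error by Freedman-Lane permutation, and reports per-cluster aging
    statistics (split-half young/old coupling, Welch t on the coupling
    difference, Spearman correlation with age).  A synthetic multi-site
    BOLD cohort generator with planted age-varying seed couplings makes
    the whole pipeline testable without any imaging download.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    Rcpp,
    stats,
    utils,
    tools,
    withr,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
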
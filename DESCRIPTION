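Package: dbca
Title: Dynamical Brain Complexity Analysis for Resting-State fMRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Voxel-wise dynamical complexity mapping of 4D BOLD images by
    sliding-window sample entropy, with mean and standard-deviation brain
    entropy (BEN) summary maps, Monte-Carlo cluster-extent corrected
    two-sample group contrasts, and complex-network analysis of regional
    brain-entropy sequences: Pearson connectivity, proportional
    thresholding, small-world and efficiency metrics normalised against
    degree-preserving random networks, and two-way group-by-threshold
    ANOVA. Includes a fully seeded synthetic-cohort generator with
    regionally controlled signal regularity for ground-truth validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    oro.nifti,
    igraph,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
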
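Package: restppi
Title: Physiophysiological Interaction Analysis for Resting-State fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Voxel-wise physiophysiological interaction (PPI) analysis of
    resting-state fMRI: canonical double-gamma hemodynamic response modelling,
    empirical-Bayes ridge deconvolution of BOLD time series to the neuronal
    level, construction of neuronal-level interaction regressors for two seed
    regions, subject-level general linear models with nuisance confounds and
    discrete-cosine high-pass drift terms, and group-level one-sample t
    inference with random-field-theory cluster p-values, sign-flip permutation
    tests and topological (cluster-level) false discovery rate control. A
    synthetic-data module generates multi-subject 4D datasets with known
    modulatory coupling so that every stage of the pipeline is testable
    without any scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    generics,
    rlang,
    RNifti,
    tibble,
    dplyr,
    tidyr,
    ggplot2,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
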
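Package: restnet
Title: Weighted Graph Analysis of Resting-State Brain Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for weighted graph-theoretical analysis
    of resting-state functional connectivity in a pain-matrix plus
    default-mode-network node set. Covers motion censoring by framewise
    displacement, nuisance regression and band-pass filtering with
    interpolation over censored frames, partial-correlation network
    estimation, global and nodal weighted graph measures normalized against
    random equivalent graphs (weight-permutation nulls), four-criterion hub
    scoring, Newman spectral modularity, and the group-comparison and
    symptom-association statistics used in case-control cohort studies.
    Includes a two-cohort synthetic data generator so the full pipeline is
    testable without raw imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    igraph,
    MASS,
    RNifti,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
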
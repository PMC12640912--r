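Package: oculopls
Title: Oculomotor Biomarkers of Cognition via Screened Partial Least Squares
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers cognitive test performance and chronological age from
    tabular oculomotor parameters (fixation, pro-saccade, anti-saccade,
    smooth pursuit and optokinetic nystagmus tasks). Provides Spearman
    rank-correlation screening with Benjamini-Hochberg false discovery rate
    control, EM-based probabilistic principal component analysis (PPCA)
    imputation of structurally missing oculomotor blocks, single-response
    partial least squares (PLS) regression with exhaustive feature-subset
    search and BIC-minimising latent-component selection under 10-fold
    cross-validation, permutation tests for group differences in correlation
    and adjusted R-squared, and a calibrated synthetic cohort generator
    emulating healthy-control and Parkinson's disease regimes with
    group-dependent oculomotor-cognition coupling.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, jsonlite, Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), mixOmics
Config/testthat/edition: 3
RoxygenNote: 7.3.3
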
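Package: neurocx
Title: Spatiotemporal Complexity of Multichannel EEG and Its Relation to
    Fluid Intelligence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes multivariate multiscale sample entropy (mMSE)
    profiles of multichannel resting-state EEG over named scalp channel
    sets, reduces them to scalar complexity features (area under the
    profile, maximum fine-scale slope, mean coarse-scale entropy and
    between-set differences), extracts a single fluid-intelligence factor
    from a battery of reasoning tests, and relates the feature table to
    the factor score by partial least squares regression with
    cross-validated component selection (first local minimum and
    randomization test) and bias-corrected bootstrap confidence intervals
    for predictor relevance.  Includes seeded generators for synthetic
    signals and cohorts with known ground truth, epoch extraction with
    amplitude-based quality control, EDF and delimited-matrix IO, and a
    reproducible end-to-end pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    MASS,
    stats,
    utils,
    tools,
    jsonlite,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    withr,
    yaml
Config/testthat/edition: 3
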
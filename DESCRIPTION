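Package: crstab
Title: Selection Stability of Prognostic Signatures under Competing Risks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for developing high-dimensional prognostic gene-expression
    signatures in a competing-risks setting and for quantifying and improving
    their selection stability. Provides componentwise likelihood-based boosting
    for cause-specific Cox and Fine-Gray subdistribution hazard models with
    mandatory unpenalized clinical covariates, subsampling-based inclusion
    frequencies, joint-selection odds ratios for flagging influential outlier
    observations, binomial regression quantifying the impact of modeling
    choices on per-feature selection, and .632+ bootstrap Brier-score
    prediction-error curves. Includes a synthetic cohort generator with known
    ground truth for validating every stage of the strategy.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    jsonlite,
    ggplot2,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    cmprsk,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
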
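Package: fdagrn
Title: Gradient-Matching Inference of Nonlinear Gene Regulatory Network Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates nonlinear ordinary-differential-equation models of gene
    regulatory networks from expression time series by functional data
    analysis. Discrete series are interpolated with not-a-knot cubic splines,
    whose derivatives convert parameter estimation into a per-gene nonlinear
    regression: sigmoid production/decay gene models are fit by matching
    modeled to spline-estimated derivatives under bounded multi-start local
    optimization. Signed regulatory architectures are recovered by weight
    thresholding, L1 regularization paths, and exhaustive enumeration of
    regulator subsets, and reconstructions are scored against signed gold
    standards with correct-fraction, positive-predictive-value, sensitivity
    and correct-sign-fraction metrics. Includes a synthetic-data module
    generating model-class benchmarks, perturb-then-relax series, and
    fixtures shaped like the Drosophila gap-gene and IRMA data sets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
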
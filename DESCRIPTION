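Package: lfdr2d
Title: One- and Two-Dimensional Local False Discovery Rate Estimation and
    Benchmarking
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Implements five procedures that control the local false
    discovery rate (fdr) for two-group feature screening: Efron's
    one-dimensional empirical-Bayes fdr with a binned logistic-spline
    estimate of the density ratio, Ploner's two-dimensional fdr on the
    (t-statistic, log standard error) plane via penalized-likelihood
    lattice smoothing together with its two conditional-expectation
    one-dimensional reductions, and Kim's two-stage marginal-then-combine
    procedure for union- and intersection-type composite nulls.  Also
    provides a Gaussian-mixture synthetic data generator, a Monte-Carlo
    oracle for the true local fdr, a repetition benchmark harness with
    confusion-matrix metrics and ROC construction, plain-text matrix I/O,
    and a small command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    splines,
    utils,
    Matrix
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
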
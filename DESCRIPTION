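Package: vbmoe
Title: Variational Bayes Mixture of Experts for sEMG Force Regression and
    Movement Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Fits a multivariate Bayesian mixture-of-experts model to
    multichannel surface electromyography (sEMG) features for simultaneous
    fingertip force regression and unsupervised movement classification.
    Inference is by variational Bayes expectation-maximization with
    Gaussian-Wishart gate posteriors, matrix-Normal-Wishart linear experts,
    automatic relevance determination over input channels, and automatic
    expert pruning via the mixing coefficients. Includes windowed
    time-domain sEMG feature extraction (MAV, WL, RMS and a zero-phase
    low-pass envelope), Student-t posterior predictive distributions with
    confidence intervals, regression and classification metrics, a seeded
    synthetic session generator for end-to-end testing, and a
    regression-based global sensitivity-analysis toolkit with Iman-Conover
    rank-correlated Latin hypercube sampling for electrode-reduction
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    lhs,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
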
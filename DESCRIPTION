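Package: betamca
Title: Maximal-Causes Latent Variable Models for Beta-Distributed
    Interval Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Latent variable models for interval-valued observations in
    (0,1), such as graded medical symptom descriptors or rescaled image
    intensities.  Binary latent causes combine through a maximum
    non-linearity that selects, per observable, both the mean and the
    variance of a Beta-distributed observation; an always-active
    background cause models the statistics when no cause is present.
    Provides exact and truncated variational expectation-maximization
    training (including an evolutionary search over latent-state
    subsets), a scalar-variance model variant, a noisy-OR Bayes-net
    baseline for binarized data with ROC/AUC evaluation, and synthetic
    benchmarks: the bars test, simulated disease-symptom profiles, and
    patch-based image denoising under Beta noise.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    png,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
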
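Package: v1robust
Title: Eigenspectra, Spatial Frequency Tuning, Predictivity and Adversarial
    Robustness of V1-Like Representations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline relating the adversarial robustness of visual
    models to V1-like properties of their internal representations.
    Implements cross-validated PCA (cvPCA) for unbiased signal eigenspectrum
    estimation from trial-structured neural data, power-law exponent fitting
    of eigenspectra, in-silico electrophysiology with Gabor patch stimuli and
    a V1 spatial-frequency similarity score against the De Valois macaque
    reference distribution, noise-corrected neural response predictivity via
    partial least squares or ridge regression with Spearman-Brown reliability
    correction, and norm-bounded projected-gradient robustness evaluation
    together with TRADES and input-gradient-regularization training
    objectives at toy scale. Synthetic generators (planted power-law
    response tensors, Gabor-bank and small random convolutional model
    adapters, linear-readout model neurons, Gaussian toy classification) make
    every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    mixOmics,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
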
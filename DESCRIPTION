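Package: riemeeg
Title: Riemannian Decoding of Consumer Preference from Multichannel EEG
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Single-trial EEG decoding of binary preference ("buy"/"no-buy")
    using spatial covariance descriptors handled on the manifold of symmetric
    positive-definite matrices. Provides the affine-invariant Riemannian
    metric and Karcher mean, per-subject Riemannian alignment, classical
    multidimensional scaling with a Nystroem out-of-sample extension, a
    seven-frequency-band ensemble of linear support-vector machines combined
    by majority voting, the multivariate Wald-Wolfowitz (minimal-spanning-tree
    runs) separability score, a wavelet-ICA artifact-cleaning chain, a grouped
    repeated-split evaluation protocol, and a seeded synthetic-data generator
    with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    optparse
Config/testthat/edition: 3
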
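Package: megdecode
Title: Interpretable Full-Epoch Multiclass Decoding for M/EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Full-epoch multiclass decoding of epoched electrophysiology
    (MEG-like) data with interpretable feature attribution. Provides a deep
    linear neural network with a learnable channel-projection first layer,
    shrinkage linear discriminant analysis on supervised (network-derived) or
    unsupervised (PCA) channel projections, sliding-window decoding baselines,
    and a six-variant permutation-feature-importance suite (temporal, spatial,
    spatiotemporal, spectral, spatio-spectral and temporo-spectral) that
    recovers where, when and at which frequencies class-discriminative
    information lives, from a single trained full-epoch model. Includes a
    synthetic MEG-like data generator with planted ground-truth structure,
    stratified splitting, PCA whitening, and signed-rank comparisons of
    decoders with Bonferroni correction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml,
    signal
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr
Config/testthat/edition: 3
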
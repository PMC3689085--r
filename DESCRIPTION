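Package: selfemg
Title: Self-Enhancing Discriminant Classification of Continuous Surface EMG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Continuous sliding-window pattern recognition of multi-channel
    surface electromyography (EMG) into hand and wrist motion classes, with
    self-enhancing Gaussian discriminant classifiers (SELDA/SEQDA) that
    incrementally update class means, class covariances and the pooled
    covariance from each newly classified testing window. Includes Burg
    autoregressive plus root-mean-square and Fourier-derived cepstral
    feature extraction, a synthetic drifting-EMG generator emulating
    cyclic contraction/rest acquisition protocols, and an evaluation
    harness with recognition-accuracy metrics, classifier-parameter drift
    diagnostics and paired method comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    readr,
    rlang,
    jsonlite,
    generics,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
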
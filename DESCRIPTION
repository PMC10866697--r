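Package: phonopop
Title: Single-Neuron Encoding and Population Decoding of Speech
    Articulatory Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing single-unit spiking activity recorded
    during natural speech production. Words are embedded in articulatory
    feature spaces (places and manners of articulation, cardinal vowels,
    syllable templates, bound morphemes, spectral bands); per-neuron
    encoding is quantified with Poisson generalized linear models (AIC,
    deviance-based D-squared, likelihood-ratio and Wald selectivity,
    Hamming-distance tuning curves); population-level coding is assessed
    with trial-matched pseudopopulations, per-dimension support-vector
    decoders scored by ROC-AUC, label-shuffle nulls, cross-epoch model
    switching and time-resolved peak-decoding statistics; and planning
    versus production population geometry is compared through PCA
    subspaces, a covariance alignment index with a Monte-Carlo random
    subspace null, and the normalized Grassmannian chordal distance.
    A seeded synthetic-session generator with planted ground truth makes
    every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
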
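Package: errpnet
Title: Error-Related Potential Detection from 2D EEG Images with an
    Attention CNN and Stacked Multi-Channel Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Single-trial detection of error-related potentials (ErrPs) in
    multichannel EEG. Continuous recordings are re-referenced (common average
    reference), band-pass filtered with a zero-phase Butterworth filter,
    optionally cleaned with ICA, epoched around feedback events and min-max
    normalized. Each single-trial channel trace is rasterized into a 224x224
    binary grayscale image and classified by an attention-based convolutional
    neural network (conv/BN/max-pool stack with a convolutional block
    attention module and a label-smoothed cross-entropy loss), trained with
    Adam, cosine learning-rate decay, minority oversampling and early
    stopping. Per-channel decisions are fused either by majority voting or by
    a learned stacking ensemble trained on out-of-fold predictions. A
    synthetic ErrP generator (triphasic frontocentral template, scalp
    attenuation, pink/white noise, optional blink artifacts) makes the whole
    pipeline testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    graphics,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
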
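Package: fnssir
Title: Decoding Motor Imagery of Force-Intensity Variation from EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for decoding motor imagery (MI) of force-intensity variation
    from multichannel EEG. Implements the full analysis and classification
    pipeline: FIR bandpass / common-average-reference / downsampling
    preprocessing, event-related spectral perturbation (ERSP) time-frequency
    analysis with Morlet wavelets, movement-related cortical potential (MRCP)
    trial averaging, a 2D electrode-plane representation of the 10-20 montage
    with distance-based interpolation, and a three-branch feature-fusion
    network (multi-scale spatial-temporal 3D convolutions, a convolutional
    auto-encoder for low-frequency denoising, and LSTM with scaled dot-product
    self-attention) trained end to end with Adam. A synthetic force-MI EEG
    generator with controllable event-related desynchronization and MRCP
    effect sizes makes every stage testable without external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    graphics,
    grDevices,
    jsonlite,
    signal,
    stats,
    utils,
    tools,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
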
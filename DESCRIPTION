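Package: usvdetect
Title: Hybrid CNN-BiLSTM Detection and Denoising of Mouse Ultrasonic
    Vocalizations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects, segments and denoises mouse ultrasonic vocalizations
    (USVs) in high-sample-rate audio recordings. Audio is converted to a
    124-band log-Mel spectrogram (1-125 kHz, ~332 frames/s); a dual-branch
    convolutional stage estimates a per-frame frequency mask which a
    bidirectional LSTM classifies frame by frame. Includes training-time
    augmentations (frequency shift, value jitter, humming/impulse line
    injection), imbalance handling by segment condensation and class-weighted
    cross entropy, interval and frequency-boundary extraction, mask-based
    spectrogram denoising, evaluation with the USV/Partial/Multi matching
    taxonomy plus local/global signal-to-noise ratios, and a synthetic USV
    simulator that produces audio with ground-truth annotations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
LinkingTo:
    Rcpp,
    RcppArmadillo
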
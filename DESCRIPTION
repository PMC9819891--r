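Package: emomap
Title: EEG and Music Emotion Analysis with Wavelet Band-Power Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how music listening shifts emotional state.
    Implements an EEG emotion-recognition pipeline (db4 wavelet denoising with
    a minimax hard-threshold rule, 4.0-45.0 Hz band-pass filtering, discrete
    wavelet sub-band decomposition into the classical delta/theta/alpha/beta/
    gamma bands, and average log power-spectral-density features from Welch
    periodograms), a music emotion-classification pipeline (a 21-dimensional
    per-clip audio feature vector: 13 MFCCs, spectral centroid and flux, zero
    crossings, RMS, tempo and pulse clarity, major/minor mode score, and
    sensory roughness), an RBF-kernel SVM harness with grid search and
    stratified cross-validation including EEG channel ranking, and
    valence-arousal emotion mapping with music-conditioned emotion-transition
    tables. Seeded generators for synthetic EEG, synthetic music clips, and
    synthetic transition records make every stage testable without external
    recordings.
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
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
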
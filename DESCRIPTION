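Package: ssveptag
Title: Decoding Frequency-Phase Tagged SSVEP Targets from Intracranial and Scalp Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and decoding pipeline for steady-state visual evoked
    potential (SSVEP) brain-computer interfaces that encode selectable targets
    by joint flicker frequency and phase. Implements three single-trial
    classifiers (a naive Fourier/phase decoder, filterbank canonical
    correlation analysis with individual calibration, and a spatiotemporal
    LCMV beamformer), the accompanying preprocessing chain (re-referencing,
    zero-phase Butterworth filtering, epoching, resampling), stratified
    cross-validated accuracy estimation across stimulation lengths, greedy
    forward electrode selection, circular phase statistics (circular standard
    deviation, two-sample Kuiper test), narrowband SNR spectra, and a
    regression-based imputation of decoding accuracy from trial-to-trial phase
    variability. A synthetic generator emulates frequency/phase-tagged
    multi-channel recordings with harmonics, phase jitter, 1/f background
    noise and localized or diffuse spatial mixing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    jsonlite,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
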
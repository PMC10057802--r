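Package: eegseg
Title: Unsupervised Per-Channel Segmentation and Anomaly Labeling of EEG
    Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Unsupervised labeling of candidate epileptiform events in
    multichannel electroencephalogram (EEG) recordings. Each channel is cut
    into overlapping windows and transformed to Fourier magnitude spectra; a
    per-recording bottleneck autoencoder learns the channel's background
    spectral repertoire, and the per-frame reconstruction error is segmented
    into discrete states by a transition-penalized Viterbi decoder with a
    generative state-hypothesis loop. Frames assigned to non-background
    states concentrate expert attention on rare high-amplitude discharges.
    Includes 16-bit European Data Format (EDF) input/output, a parser for
    CHB-MIT-style seizure annotation summaries, frame- and event-level
    evaluation metrics, a synthetic EEG generator with planted spike-wave
    events, and batch orchestration with reproducible plain-text outputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    parallel,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
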
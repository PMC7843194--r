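Package: eegsdae
Title: Denoising-Autoencoder Feature Extraction and Granger-Causal
    Connectivity for Multichannel EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Adaptive feature extraction for noisy multichannel EEG and
    directed connectivity inference between brain areas. Recordings are
    spatially sharpened with a four-neighbour surface Laplacian, compressed
    per area by a two-stage stacked denoising autoencoder whose hidden-layer
    sizes are selected by a criterion balancing reconstruction error against
    low-frequency short-time Fourier energy, scored by the ratio of the
    dominant in-band spectral peak to the mean in-band power (RPFA), and fed
    to conditional Granger causality with circular-shift permutation
    significance to produce directed area-to-area connectivity graphs. A
    ground-truthed synthetic EEG generator, EDF input and a command-line
    pipeline are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    jsonlite,
    signal,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
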
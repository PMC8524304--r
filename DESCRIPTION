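Package: platt
Title: Low-Latency Auditory Dynamic-Range Manipulation and Speech
    Recognition Threshold Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Implements PLATT, a low-latency dynamic-range manipulation
    scheme built on an auditory-motivated complex fourth-order Gammatone
    filterbank with trivial time-domain resynthesis. Spectral frames are
    decomposed into a base layer and four spectral-modulation difference
    layers; the 2-4 ERB modulation band can be expanded while coarser
    dynamics are conditionally compressed into a configurable output
    dynamic range. Also provides a functional class-D hearing-loss model
    (level uncertainty and frequency limiting applied to log-Mel
    features), seeded generators for calibrated synthetic test signals
    (tones, speech-shaped and co-modulated fluctuating maskers, a
    synthetic word corpus), and a scaled-down speech-recognition-threshold
    evaluation harness based on recognition result maps over training and
    testing signal-to-noise ratios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
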
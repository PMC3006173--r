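Package: lfpdecoder
Title: Decoding Movement Direction from Multichannel Local Field Potentials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decodes movement target direction from trial-epoched multichannel
    local field potentials (LFP) recorded during center-out reaching. Implements
    sub-band decomposition with linear-phase Blackman-window FIR filters and
    Hilbert envelopes, Common Spatial Patterns (CSP) feature extraction by
    generalized eigendecomposition of class covariances, and an
    error-correcting-output-codes (ECOC) fusion of a bank of Fisher linear
    discriminants into an eight-class direction decision. Ships the full
    evaluation protocol (decoding power, Fisher-Lee circular correlation,
    repeated stratified cross-validation with the Nadeau-Bengio corrected
    t-test, sliding-window time courses, cross-session transfer, channel- and
    trial-subset curves), a spike-count decoding path with a regularized-LDA
    baseline, and a synthetic generator of direction-tuned LFP and cosine-tuned
    Poisson spike trains so every stage is testable without animal recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
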
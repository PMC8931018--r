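Package: lipdecode
Title: Lip-Language Decoding from Triboelectric Sensor Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for decoding silent speech from flexible triboelectric
    lip-motion sensors. Provides a calibrated simulator of the
    contact-separation sensor's electrical response (open-circuit voltage,
    short-circuit current, series/parallel combination, load curves,
    durability), a seeded generator of synthetic lip-motion utterances with
    paired sound envelopes, the signal-conditioning chain used for such
    recordings (zero-phase low-pass filtering, amplitude normalization,
    onset segmentation, short-time Fourier analysis, timing statistics),
    and a dilated gated-recurrent-unit network with prototype-learning
    classification alongside a softmax baseline, together with an
    evaluation harness for confusion analysis, small-sample sweeps,
    feature-space separability, speaker verification and command mapping.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    signal,
    stats,
    utils,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
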
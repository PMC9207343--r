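Package: kuracomplex
Title: Functional Connectivity and Signal Complexity in a Kuramoto Model of
    MCI-AD EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to study the relationship between EEG functional
    connectivity and signal complexity with a connectivity-driven Kuramoto
    mean-field simulator. Implements weighted phase lag index (WPLI)
    connectivity estimation from multichannel EEG, alpha-band extraction by
    Daubechies wavelet (MODWT) decomposition, a 21-oscillator Kuramoto
    simulator coupled through a connectivity matrix with a central-region
    lesion transform, three complexity estimators (Lempel-Ziv complexity,
    Higuchi's fractal dimension, fluctuation-based dispersion entropy),
    group-comparison statistics with FDR correction, and a synthetic-data
    generator emulating control and patient cohort structure so the whole
    pipeline is testable without restricted clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
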
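Package: cardiorng
Title: True Random Numbers from Electrocardiogram Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts cryptographic-grade random bytes from single-lead
    electrocardiogram (ECG) recordings. The signal is cleaned with a
    zero-phase 0.67-45 Hz bandpass, split into one-heartbeat windows
    around detected R-peaks, decomposed with a multilevel discrete
    wavelet transform, and the fractional parts of the approximation
    coefficients are quantized into bytes. Includes a seeded synthetic
    ECG generator with ground-truth beat annotations, an ENT-style
    randomness battery (entropy, chi-square, arithmetic mean,
    Monte-Carlo pi, serial correlation), Hamming-distance
    distinctiveness analysis against the binomial model, and bias and
    throughput reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
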
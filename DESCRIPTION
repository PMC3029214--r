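Package: voicelevel
Title: Automated Grading of Voice Disorder Severity in Children with
    Cochlear Implants or Hearing Aids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for automated four-level grading of voice disorder
    severity from isolated-word recordings of children with cochlear
    implants or hearing aids. Extracts frame-based acoustic features
    (fundamental frequency, formants, relative intensity, a spectral
    nasality score, approximate entropy) and word-based nonlinear and
    wavelet features (Higuchi fractal dimension, largest Lyapunov
    exponent, Gaussian-wavelet coefficient energies), classifies each
    word with banks of continuous left-right hidden Markov models and a
    word-feature multilayer perceptron, and fuses the per-word
    classifiers by majority voting, linear log-likelihood combination,
    or a stacked meta-classifier. Includes a source-filter synthesizer
    that generates labelled corpora with severity-dependent pitch,
    jitter, shimmer, nasality and noise for end-to-end validation, and a
    random-subsampling cross-validation harness with per-level accuracy
    reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    graphics,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
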
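Package: bulbwave
Title: Spectral and Behavioral Quantification of Olfactory Bulb Network Suppression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify pharmacological suppression of olfactory bulb
    (OB) local field potential activity and its behavioral correlates.
    Provides a seeded generator of synthetic OB slice recordings
    (1/f background plus a beta-band resonance, with a time-varying
    multiplicative power gain as ground truth), the classical spectral
    pipeline used for such recordings (20-s segments every 5 min, Hamming
    windowed periodograms over 1-50 Hz, band integration, normalization to
    the control epoch, peak frequency, and time-courses), a nonparametric
    statistics battery (Kruskal-Wallis, Dunn, Friedman, Wilcoxon signed
    rank) implemented from formulas with exact small-sample behavior, and a
    censoring-aware analysis of hidden-food olfactory latency assays with
    motivation and motor controls.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    pracma,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
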
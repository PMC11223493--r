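Package: coapore
Title: Nanopore Resistive-Pulse Quantification of Cyclic Oligoadenylate
    Stoichiometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of single-molecule nanopore recordings of cyclic
    oligoadenylates (cOAs), the second messengers of type III CRISPR-Cas
    systems. Provides resistive-pulse event extraction from ionic-current
    traces (zero-phase low-pass filtering, median-conserving decimation,
    open-pore threshold detection), dwell-time and blockade distribution
    fitting with bootstrap uncertainty, a one-dimensional convolutional
    neural network for per-event stoichiometry classification with
    trace-grouped cross-validation and a k-nearest-neighbour baseline,
    event-rate-corrected mixture composition estimates with prediction
    intervals, absolute enzymatic yield computation, LC-MS peak-area
    concentration estimators, equivalence testing (TOST), and a synthetic
    trace simulator with ground-truth annotations so the whole pipeline is
    testable without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    Rcpp,
    signal,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    class,
    withr,
    fitdistrplus,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
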
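Package: iacdfc
Title: Dynamic EEG Functional Connectivity via Instantaneous Amplitude Correlation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sample-by-sample amplitude-envelope functional connectivity for
    multichannel resting-state EEG. Band-limits recordings into the canonical
    frequency bands with zero-phase FIR filters, computes the instantaneous
    amplitude correlation (IAC) between every electrode pair from
    leakage-corrected (orthogonalized) Hilbert envelopes, collapses the
    per-sample adjacency matrices to a global average-strength time series,
    summarises that series by its first- to fourth-order cumulant-based
    descriptors (mean, standard deviation, skewness, kurtosis), and compares
    groups with FDR-corrected Mann-Whitney tests plus a Pearson screen against
    a dose covariate. Includes a synthetic-cohort generator with controllable
    envelope coupling, burst dynamics and channel mixing so every stage has a
    recoverable ground truth, plus EDF and delimited-text I/O and a
    command-line driver for the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    e1071,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
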
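Package: sersignal
Title: Background Removal and Signal Identification for Time-Resolved
    SERS Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools for analysing time series of surface-enhanced Raman
    scattering (SERS) spectra: removal of a strong, time-varying
    background by median-based time-frequency block estimation,
    false-discovery-rate controlled detection of transient analyte
    signals, merging of runs of consecutive detections into signature
    signals, and frequency-shift-tolerant matching of signatures across
    experiments.  Includes a seeded simulator of SERS-like spectra with
    known ground truth and a command-line interface for running the full
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    jsonlite,
    stats,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
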
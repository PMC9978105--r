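Package: erpsse
Title: Soft-DTW Single-Subject ERP Averaging and Transformer Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Feature extraction and classification for N400 event-related
    potentials (ERPs). Implements differentiable Soft Dynamic Time Warping
    (Soft-DTW) with exact dynamic-programming forward and backward passes,
    Soft-DTW barycenter (Frechet mean) averaging of time series, and the
    single-subject short-distance ERP averaging pipeline (SSE) that replaces
    arithmetic trial averaging with per-channel Soft-DTW barycenters over
    DTW-nearest trial neighbourhoods within each (subject, label) group.
    Includes a compact transformer encoder classifier for multichannel
    epochs, subject-wise k-fold cross-validation, a seeded generator of
    N400-like synthetic epoch datasets, and a plain-text epoch store with a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    data.table,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
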
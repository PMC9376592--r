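Package: seizegraph
Title: Graph Convolutional Seizure Prediction from Scalp EEG
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An end-to-end, patient-specific seizure prediction pipeline that
    models each 60 s window of multi-channel scalp EEG as a weighted graph.
    Bipolar-montage channels are graph nodes carrying spectral (wavelet-packet
    band energy) and time-domain (Hjorth, higher-order crossings, difference,
    differential entropy, fractal dimension) features; edges combine scalp
    geodesic distance with spectral coherence. A compact three-layer graph
    convolutional network with the self-loop renormalization trick classifies
    windows as preictal or interictal, trained with SMOTE oversampling, a
    gradient-harmonizing loss and Adam under per-subject leave-one-seizure-out
    cross-validation. A bundled synthetic-EEG cohort generator with
    controllable preictal band-power and synchrony shifts makes every stage
    testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    data.table,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
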
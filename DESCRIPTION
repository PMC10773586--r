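Package: eegtda
Title: Seizure Detection from Multichannel EEG via Persistent Homology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Automatic detection of epileptic seizures from multichannel
    scalp EEG using topological data analysis. Two-second EEG windows are
    converted into Euclidean point clouds by a channel-folding construction,
    Vietoris-Rips persistent homology (dimensions 0 and 1, Z/2 coefficients)
    summarizes each cloud as a barcode, barcodes are rasterized into
    fixed-size images and classified seizure versus interictal, and
    performance is evaluated both per segment (accuracy, sensitivity,
    specificity, precision, F1) and per seizure event (leave-one-event-out
    detection latency). Includes a synthetic annotated-EEG generator and a
    minimal EDF/EDF+ reader and writer so the whole pipeline runs without
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    nnet,
    png,
    signal,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
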
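Package: atpfret
Title: Single-Cell Analysis and Simulation of Organelle-Targeted FRET ATP
    Biosensor Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantification pipeline for ratiometric CFP/YFP FRET ATP
    biosensor time-lapse recordings from single cells: background
    subtraction, YFP/CFP ratiometry, photobleach correction by exponential
    curve fitting, normalization, per-cell feature extraction (basal level,
    transient peak, onset of depletion, minimum, maximal signed changes,
    peak width), and a two-axis metabolic fingerprint (response to glucose
    removal versus response to oligomycin) that classifies the metabolic
    setting of individual cells as glycolytic or oxidative. Includes a
    compartmental ordinary-differential-equation model of cytosolic,
    mitochondrial and endoplasmic-reticulum ATP with a reversible,
    mitochondria-coupled hexokinase, a fluorescence forward model (sensor
    occupancy, channel bleed-through, photobleaching, background, noise)
    for fully synthetic test data, and Pearson/Manders colocalization with
    Costes automatic thresholding for dual-channel images.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    stats,
    utils,
    graphics,
    yaml,
    jsonlite,
    rlang,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    pracma,
    tiff,
    withr
Config/testthat/edition: 3
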
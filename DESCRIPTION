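Package: fretPolarity
Title: Spatiotemporal Quantification of Ratiometric FRET Biosensor Movies
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to turn two-channel (donor/acceptor) TIRF time-lapse
    movies of ratiometric FRET biosensors into quantitative readouts of
    cell polarity, motility and phagocytosis. Provides bead-based channel
    registration, ratio-image computation with validity masking, automated
    cell segmentation and tracking, longitudinal-axis activity profiles
    with 20-bin reductions, kymographs, peripheral edge-band sampling and
    polar maps, peak-activity oscillation statistics (pole dwell times,
    wave durations, switch counts), migration phase classification and
    velocity measures, phagosomal FRET traces with engulfment timing, and
    a synthetic-movie generator with full ground truth for validating
    every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    EBImage,
    tiff,
    jsonlite,
    yaml,
    pracma
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: CellBiology, Visualization, Software
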
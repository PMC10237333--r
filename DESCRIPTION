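Package: fretlapse
Title: Single-Cell FRET Biosensor Trace Analysis for Yeast Nutrient Transitions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Ratiometric quantification of intramolecular FRET biosensor
    signals (such as the AKAR3-EV kinase activity reporter) in single yeast
    cells: spectral bleedthrough correction, baseline normalization of
    time-lapse FRET ratios, per-cell response features, saturation-kinetics
    dose-response fitting, k-means clustering of response trajectories,
    sliding-window growth-rate estimation from plate-reader optical density
    curves, and control-strain corrected flow-cytometry FRET levels. A
    forward simulator generates microscopy trace sets, cytometry experiments
    and growth curves with known ground truth so every stage of the pipeline
    can be validated end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    zoo
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    jsonlite
Config/testthat/edition: 3
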
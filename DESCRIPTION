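Package: tapetrace
Title: Decoding Time-Resolved Transcriptional Activity from Intracellular Protein Tape Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational readout of intracellular protein "tape" fibers that
    grow bidirectionally from a nucleation point and encode time along their
    arclength. Provides a ground-truthed forward simulator of tape growth,
    dye timestamping, promoter-driven signal deposition and anisotropic
    confocal imaging; classical 3D instance segmentation of fibers and somata
    with quality-control filters; centerline extraction, extrapolation and
    geometry; intensity profiling along centerlines; space-to-time decoding
    via timestamp anchors and monotone transfer functions; and per-cell
    waveform analytics (peak features, line-length fluctuation, time-lagged
    correlation and coupling-mode classification).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
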
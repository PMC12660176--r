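Package: quantalmap
Title: Quantal Imaging and Photoconversion Analysis of Synaptic Release Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for optical quantal imaging and photoconversion
    pulse-chase experiments at the Drosophila larval neuromuscular junction.
    Detects fluorescent active-zone and postsynaptic-density puncta on
    max-projected confocal stacks, detects single-vesicle GCaMP release events
    in time-lapse movies, assigns events to release sites by centroid
    proximity, separates evoked from spontaneous fusion by frame coincidence,
    and maps per-active-zone release probability and spontaneous release rate.
    Classifies synapse age from two-colour photoconvertible glutamate-receptor
    labels, estimates scaffold-protein turnover half-lives from photoconverted
    signal decay, and computes puncta morphometrics, colocalization and
    density statistics. Includes a synthetic-data generator that renders
    ground-truth neuromuscular-junction imagery (puncta stacks, stimulation
    movies, photoconversion time series) for validation and parameter-recovery
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    grDevices,
    graphics,
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
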
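Package: mapanchor
Title: Order and Orient Genome Assembly Scaffolds Using Multiple Genomic Maps
Version: 0.1.0
Authors@R:
    person("Map", "Anchor Developers", email = "mapanchor@example.org",
           role = c("aut", "cre"))
Description: Anchors genome assembly scaffolds into chromosome-scale
    pseudomolecules by maximizing weighted colinearity (longest monotonic
    subsequence) against one or more genomic maps (genetic, optical, or
    comparative/synteny maps). Provides map parsing and linkage-group
    clustering with chimera alerts and outlier-marker removal, a two-phase
    optimizer (spectral orientation plus travelling-salesman ordering,
    refined by an elitist genetic algorithm with partially mapped
    crossover), genome release as FASTA/AGP/CHAIN with summary statistics,
    recombination-rate-based gap size estimation via cubic splines, and a
    simulation harness with an LMS-based accuracy metric.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
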
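Package: nemapaint
Title: Design and Quantification Toolkit for Multiplexed Oligopaint DNA FISH
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Designs genome-scale Oligopaint DNA FISH libraries: mines 42-nt
    homology sequences under uniqueness, melting-temperature, GC, repeat and
    secondary-structure filters; subsamples them to even density; assembles
    150-nt primary oligos with a nested barcode architecture enabling
    chromosome, 3 Mb and 500 kb sub-pool amplification; wires bridge and
    detection oligos into combinatorial color codes; and quantifies 3D
    chromosome-territory volumes and pairwise overlaps from image stacks.
    Synthetic genome and nucleus-image simulators with recorded ground truth
    make the whole pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
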
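Package: spheroidbridge
Title: Bridging Time-Lapse Spheroid Imaging and Off-Lattice Growth Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end in silico analysis of multicellular tumour spheroids
    grown in soft agar. Segments phase-contrast time-lapse images into
    equivalent circles, estimates cell counts by sphere-packing bounds
    (simple cubic and face-centred cubic), fits Richards generalized
    logistic growth curves and characterizes cohorts on a PCA feature
    plane, replicates each spheroid with a lattice-free cellular-particle
    simulator (pairwise forces, nutrient budget and radial diffusion,
    Monod-type cell-cycle control, generation tracking), calibrates the
    simulator to an observed growth curve via a relative log-error
    bridge, and derives virtual inner proliferative activity from
    per-generation censuses.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics,
    EBImage,
    minpack.lm,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    tiff,
    png
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
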
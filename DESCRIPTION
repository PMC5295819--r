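Package: tissuecanvas
Title: Growing Polarised Tissue Simulation and Cell Polarity Quantification
Version: 0.1.0
Authors@R:
    person("Morphogenesis", "Lab", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates the growth and out-of-plane deformation of polarised
    tissue sheets ("canvases") driven by declarative growth-regulatory
    networks, including a catalogue of surface, areal, directional and
    orthogonal tissue-conflict models with ablation variants; models cell
    division on the growing canvas for inferring growth orientation from
    wall-age patterns; and quantifies per-cell PIN polarity from two-channel
    images via boundary-band intensity-weighted vector sums, with synthetic
    ground-truth image generation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    deldir,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
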
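Package: cryptdyn
Title: Multiscale Simulation of Wnt/Hippo Signalling in Intestinal Crypts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Agent-based simulation of intestinal crypt homeostasis coupling a
    per-cell Wnt/beta-catenin signalling network extended with Hippo-mediated
    sequestration of cytoplasmic beta-catenin by phosphorylated YAP, a
    restriction-point cell-cycle module driven by transcriptional beta-catenin,
    and cell-centre mechanics on an unrolled periodic crypt with Voronoi cell
    volumes triggering contact inhibition. Supports imposed Wnt gradients (read
    at birth or continuously updated) and an internal division-based Wnt model
    with a basal reservoir, wild-type proliferation and velocity profiles,
    emergent Wnt gradients, and APC double-mutant washout ensembles with
    binomial confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
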
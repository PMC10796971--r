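Package: arborcsr
Title: Subcellular Center-Surround Analysis in Bipolar Cell Axonal Arbors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compartmental cable modelling of retinal bipolar cell axonal
    arbors with stochastic conductance-based synapses, per-ribbon
    center-to-surround ratio (CSR) analysis, a difference-of-Gaussians
    bipolar-subunit model of ganglion cell excitation with constrained
    fitting and cross-validation, and a combined pipeline that predicts
    type-specific surround suppression of retinal ganglion cell excitatory
    responses from the CSR quartiles of the bipolar cell model. Includes
    synthetic generators for bipolar and ganglion cell morphologies and
    spot-size response curves so every stage is testable without external
    data.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
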
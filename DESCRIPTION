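Package: somatomap
Title: Self-Organizing Somatotopic Map Plasticity with Excitatory and
    Inhibitory Synaptic Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Firing-rate simulation of primary somatosensory cortical area 3b
    as a pair of two-dimensional lattices: a three-digit skin input layer
    forward-connected to a cortical layer of excitatory/inhibitory column
    pairs.  All four connection types (afferent and lateral, excitatory and
    inhibitory) are plastic under a covariance learning rule with competitive
    postsynaptic resource normalization.  The package implements the full
    experimental protocol (baseline refinement, simulated digital syndactyly,
    syndactyly release, and matched stimulation controls), two-step receptive
    field mapping by single-node probe trials, and the derived analyses:
    receptive field centroids, extents, orientation, overlap, intracolumnar
    excitatory-inhibitory centroid divergence, and representational border
    band width.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
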
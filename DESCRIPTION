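Package: cmcircuit
Title: Canonical Microcircuit Neural Mass Models: Simulation, Response
    Classification, and Bifurcation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates a generalized canonical-microcircuit neural mass model
    of the Jansen-Rit family with three interacting populations (pyramidal
    cells, excitatory and inhibitory interneurons) and architectural switches
    that morph it into two-population variants with direct excitatory feedback
    and optional recurrent inhibitory self-feedback.  Provides a compiled
    Heun integrator for single circuits and coupled networks, classification
    of stimulus responses into nonresponsive, transfer, and memory behaviors
    (fingerprints and dynamic function maps over the synaptic-gain plane),
    equilibrium-curve continuation with fold and Hopf detection, two-parameter
    tracing of bifurcation loci, and a six-node sentence-parsing network
    demonstration built on the circuit's gating and working-memory operations.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
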
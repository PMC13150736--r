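Package: nnmo
Title: Evolving Recurrent Neural Network Model Objects and Their Functional Symmetry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A heuristic model of biological evolution in which the evolving
    agents are small fully connected recurrent neural networks ("neural
    network model objects", NNMOs) trained by a mirrored random-search
    algorithm to recognise stimuli in a quasi-random discrete event stream.
    Provides the network dynamics and goal (fitness) function, seeded stream
    generators for recognition tasks such as A3 and C4, the (1+2) mirrored
    random-search evolutionary trainer with ensemble and
    trajectory-divergence experiments, the functional-symmetry machinery
    (sign-change and hidden-neuron-permutation transforms, the 2^K * K!
    cluster-count prediction, orbit canonicalisation, distance and cluster
    analysis of ensembles in structure space), and the complexity-reduction
    procedure (iterative smallest-magnitude synapse removal with retraining,
    network compaction, randomised-synapse negative control, and
    minimal-network-size search).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    graphics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
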
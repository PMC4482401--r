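Package: dendrim
Title: Discriminable Dendritic Input Patterns from Neuron Morphology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies the number of discriminable coincident synaptic input
    patterns (M) that a dendritic tree can support, starting from an SWC
    reconstruction. Spine counts are inferred from the Cuntz scaling law
    relating total dendritic length, volume and synapse number, allocated to
    branches in proportion to branch length, and placed equidistantly or
    uniformly at random. Somatic voltage waveforms elicited by random
    coincident activation patterns are produced by a configurable surrogate
    simulator (double-exponential AMPA/NMDA kernels with supralinear NMDA
    clustering), quantized to patch-clamp precision, and grouped with a
    disjoint-set connected-components criterion; a stochastic plateau search
    estimates the per-branch repertoire size, a genetic algorithm tunes five
    biophysical parameters, and the resulting per-branch values are summarised
    by an a*n*log(n) + b predictive law. Includes the permutation and
    rank-based statistics used for comparative analyses across cells, plus
    synthetic morphology and waveform generators for fully offline use, and
    an exporter for NEURON-compatible input file bundles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
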
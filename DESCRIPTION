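Package: spikedecoder
Title: Decoding Spatiotemporal Tactile Stimulation Patterns from Cortical Spike Trains
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for single-neuron and population
    decoding of spatiotemporal tactile stimulation patterns from cortical spike
    responses. Builds kernel density estimates of evoked firing with
    cost-optimised Gaussian bandwidths, segments the compound density into
    peak-defined time windows, classifies bootstrap-combined responses with a
    k-nearest-neighbour decoder (with shuffled-label controls and greedy
    cooperative population decoding), detects sensory-evoked and pattern-evoked
    local field potential events, and segments electrocorticogram recordings
    into synchronized and desynchronized brain states for state-conditioned
    decoding. Includes seeded generators for all synthetic inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
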
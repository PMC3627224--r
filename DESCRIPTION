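Package: thetaflick
Title: Theta-Cycle Assembly Flickering and Pyramidal-Interneuron Coupling Plasticity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for extracellular hippocampal recordings during
    goal-directed spatial learning: behavioral-state segmentation and
    oscillation detection from the local field potential, occupancy-normalized
    place-field rate maps with coherence and sparsity screens, per-theta-cycle
    population-vector scoring of old- versus new-map assembly expression
    (Fisher r-to-z), classification of interneurons by the association of
    their instantaneous firing rate with assembly expression,
    cross-correlogram detection of monosynaptic pyramidal-to-interneuron
    connections with spike-transmission probability and latency tracked
    across sessions, and predictors of connection change (20 ms pairing
    events, goal-area split, Gaussian spike-density coincidence). Includes a
    synthetic five-session generator with known latent map states, place
    fields and plastic connections that provides ground truth for every
    estimator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
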
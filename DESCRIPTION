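Package: snnmorph
Title: Spiking Neural Network Modeling of EEG Under Morphing Sound Therapy
Version: 0.1.0
Authors@R: person("snnmorph", "maintainers", email = "maintainers@example.org",
    role = c("aut", "cre"))
Description: Tools to study longitudinal EEG recorded around a tinnitus
    sound-therapy protocol with a brain-inspired spiking neural network:
    Step Forward spike encoding with threshold optimization, mapping of
    scalp channels into a 3D neuron grid at anatomical coordinates,
    distance-dependent small-world initialization, leaky integrate-and-fire
    dynamics with spike-timing-dependent plasticity, trained-model
    subtraction with retention of the largest relative connectivity
    changes, and ten-zone scalp-region summaries with a hemispheric
    dominance index. Also provides the stimulus side of the protocol
    (parametric tinnitus-avatar synthesis and stepped cross-fade morphing
    into environmental sound) and a synthetic-EEG generator with planted
    lagged couplings for ground-truth recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
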
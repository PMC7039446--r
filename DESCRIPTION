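Package: pspm
Title: Pre-Synaptic Pool Modification Learning for Spiking Neural Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulators for leaky integrate-and-fire (LIF) and probabilistic
    integrate-and-fire (PIF) recurrent spiking networks, together with the
    Pre-Synaptic Pool Modification (PSPM) supervised learning rules that tune
    synaptic weights so that a network reproduces a set of target spike
    trains. Includes the dynamic-programming spike matcher used to pair
    reference and observed spikes, Gaussian-kernel (van Rossum style) spike
    train distances, inter-spike-interval comparisons, and neuronal-avalanche
    criticality analysis (power-law maximum-likelihood fits and the
    crackling-noise scaling relation). Experiment runners reproduce the
    four-configuration learning study and the PIF-to-LIF criticality transfer
    at configurable scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
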
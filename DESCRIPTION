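Package: wmnet
Title: Working-Memory Spiking Networks Driven by Short-Term Synaptic Facilitation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Simulates recurrent networks of leaky integrate-and-fire neurons
    with exponential postsynaptic currents and Tsodyks-Markram short-term
    plasticity on all excitatory-to-excitatory synapses, the substrate of
    synaptic working-memory models. Neurons are advanced on a fixed time grid
    with an exact propagator; synaptic facilitation and depression are updated
    event-wise in closed form at presynaptic spike times. Includes structured
    selective-population connectivity, Gaussian piecewise-constant background
    drive, stimulation protocols for item loading and readout, population-spike
    detection, firing-rate-difference readouts, memory-capacity counting, and
    the analytic capacity estimate based on the facilitation limit cycle.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
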
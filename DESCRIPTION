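Package: netburst
Title: Network Bursts in Adaptive Exponential Integrate-and-Fire Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analytic prediction of collective network bursts
    in populations of adaptive exponential integrate-and-fire (aEIF) neurons
    coupled by delayed alpha-shaped synaptic currents on random directed
    graphs.  Provides generators for fixed and Gaussian in-degree digraphs, a
    vectorized fixed-step network simulator, spike-raster burst detection and
    statistics, and a self-consistent "equivalent autapse neuron" model that
    predicts burst onset and termination thresholds, spikes per burst, burst
    duration and interburst interval without simulating the network, using
    nullcline geometry and the lower branch of the Lambert W function.  A
    parameter-space explorer screens large numbers of neuron parameter sets
    through biological validity filters and summarizes how burst properties
    correlate with the underlying neuronal parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pracma,
    deSolve,
    withr,
    optparse
Config/testthat/edition: 3
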
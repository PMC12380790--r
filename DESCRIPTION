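Package: tcmdbs
Title: Thalamo-Cortical Spiking Network Model of Deep Brain Stimulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulator for a six-population thalamo-cortical spiking
    network model of deep brain stimulation (DBS). Populations of
    Izhikevich neurons (three excitatory cortical layers, cortical
    interneurons, thalamocortical relay and thalamic reticular nuclei)
    are coupled all-to-all through Tsodyks-Markram short-term plastic
    synapses with conduction delays, driven by Gaussian membrane and
    threshold noise, and stimulated by a periodic intracellular DBS
    current injected into the deep cortical layer. Includes a compiled
    vectorized engine, pure-R reference engines for validation, and
    analysis utilities (population synchrony, beta-band power, raster
    plots) that quantify the desynchronizing effect of high-frequency
    (130 Hz) versus low-frequency (20 Hz) stimulation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    yaml,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
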
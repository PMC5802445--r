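Package: avalanchr
Title: Neuronal Avalanche and Branching-Process Analysis of Calcium-Imaging
    Population Activity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: End-to-end analysis of two-photon calcium-imaging population
    activity in the neuronal-avalanche framework: AR(1) deconvolution of
    dF/F traces to spike-rate rasters, inter-spike-interval-preserving
    surrogate rasters, shuffle-corrected pairwise correlation and event
    synchronization, spatiotemporal avalanche extraction with log-binned
    power-law fits, Kolmogorov-Smirnov distance and size-duration scaling,
    temporal and spatial branching parameters with new/repeat decomposition,
    single-neuron burst statistics, and a persistent-burst-removal
    intervention. Includes a branching-process raster generator with
    controllable cascade propagation and per-neuron burst persistence so the
    whole pipeline is testable against closed-form criticality benchmarks,
    and a statistics layer reproducing normality-gated two-group and
    multi-group comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
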
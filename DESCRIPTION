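Package: cacf
Title: Coherence-Adaptive Clutter Filtering for Ultrasound Color Flow Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and processing toolkit for coherence-adaptive clutter
    filtering (CACF) in ultrasound color flow Doppler imaging. Generates
    point-scatterer flow phantoms (plug and parabolic flow, bulk tissue motion)
    imaged by a focused curvilinear array, injects thermal noise and spatially
    incoherent moving clutter into per-element radio-frequency channel
    ensembles, designs projection-initialized IIR clutter filter banks for
    short slow-time ensembles, computes short-lag spatial coherence (SLSC) of
    filtered channel signals, estimates axial velocity by the 2-D
    autocorrelation (Kasai) method, and selects per pixel the clutter filter
    that maximizes local spatial coherence. Includes velocity bias/standard
    deviation image-quality metrics and config-driven experiment runners.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
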
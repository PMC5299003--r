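Package: benthifilter
Title: Benthic Sulfide Filter Fluxes from Voltammetric Microprofiles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies the benthic sulfide filter of seasonally euxinic
    basins from raw measurements to a regional mass balance. Processes
    cyclic voltammograms from gold-amalgam microelectrodes into calibrated
    porewater concentrations (including polysulfide speciation from the
    double sulfide peak), computes diffusive fluxes across the
    sediment-water interface with Fick's first law and a modified
    Weissberg tortuosity correction, estimates total sulfide fluxes from
    benthic chamber incubations, and upscales station fluxes to a
    basin-scale sulfur budget. A steady-state reaction-diffusion
    generator produces synthetic porewater profiles, voltammograms and
    chamber series with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
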
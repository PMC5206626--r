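Package: streamghg
Title: Stream Network Methane and Carbon Dioxide Emission Upscaling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates and upscales diffusive methane and carbon dioxide
    emissions from headwater stream networks. Provides the physical-chemistry
    kernel (freshwater Schmidt numbers, k600 normalisation, Henry's-law
    equilibrium concentrations, diffusive flux, CO2-equivalents), gas transfer
    velocities from whole-stream propane tracer injections with
    groundwater-dilution correction, elevation-based discretisation of a
    stream network into reaches, daily drainage-area discharge scaling,
    log-linear regression models predicting water velocity and k600 from
    discharge and channel slope with smearing bias correction, reconstruction
    of reach-scale gas concentration fields from sparse spatial surveys and
    temporally resolved anchor stations, per-reach daily flux integration with
    hot-spot and hot-moment category summaries, and a synthetic catchment
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
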
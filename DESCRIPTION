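Package: mbcti
Title: Low-Frequency Conductivity Imaging from B1 Phase and Multi-b-Value
    Diffusion MRI
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Reconstructs high-frequency (Larmor) electrical conductivity
    from a B1 transceiver phase map by inverting a stabilized
    convection-reaction partial differential equation, fits a constrained
    multi-compartment model to multi-b-value diffusion-weighted MRI
    signals, and decomposes the conductivity into an apparent
    extracellular ion concentration, a low-frequency mean conductivity,
    and a low-frequency conductivity tensor. Includes a synthetic
    piecewise-homogeneous brain phantom generator so that every stage of
    the pipeline can be verified end-to-end without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    RNifti,
    oro.nifti,
    minpack.lm,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
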
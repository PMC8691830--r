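Package: vasokin
Title: Kinetic Modelling of Vasoactive-Probe Hemodynamic Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward simulation and inverse fitting of a two-compartment
    kinetic model for vasoactive molecular imaging probes that are activated
    by extracellular enzymes such as fibroblast activation protein (FAP).
    Provides closed-form and numeric solutions of the probe
    infusion/activation/efflux system, synthetic 4D hemodynamic phantom
    generation with known ground truth, MRI-style preprocessing (temporal and
    spatial smoothing, global normalization, percent signal change), ROI- and
    voxel-level nonlinear least-squares estimation of enzymatic activation
    rates with jackknife error maps and significance testing, detection-limit
    simulation, and four-parameter Hill dose-response analytics for the
    companion receptor-activation bioassay.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
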
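Package: hexamertools
Title: Single-Molecule and Structural Quantification for Hexameric AAA+ Histone Chaperones
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and quantification tools for single-molecule and
    structural studies of hexameric AAA+ ATPase histone chaperones.
    Includes pseudo-AFM image simulation from atomic models by exact
    hard-contact dilation with a sphere-capped conical tip; high-speed
    AFM movie analysis (particle FWHM statistics, per-frame ring-state
    classification, dwell-time rate estimation with discrete-sampling
    correction, subunit-activation randomness tests); DNA-curtain movie
    quantification (kymographs, multi-Gaussian binding-site fitting with
    BIC model selection, flow-off validation, fraction bound, binding
    position statistics); ensemble assay fits (ligand-depletion
    anisotropy binding, steady-state ATPase rates) and crosslinking
    mass-spectrometry result filtering; structural geometry metrics
    (superposition, domain centroids, inter-domain distances and angles,
    spiral rise, pore profile); and seeded synthetic-data generators for
    all of the above with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    tools,
    bio3d,
    tiff,
    jsonlite,
    minpack.lm,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
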
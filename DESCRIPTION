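Package: lfcyto
Title: Digital Twin of a Light-Field Imaging Flow Cytometer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Wave-optics simulation and reconstruction pipeline for Fourier
    light-field imaging flow cytometry. Builds hybrid point-spread-function
    stacks for a microlens-array Fourier light-field train, generates
    synthetic flowing phantoms (fluorescent microspheres and multi-organelle
    cells) rendered as stroboscopically illuminated camera frames with an
    sCMOS noise model, reconstructs 3D volumes by Richardson-Lucy
    deconvolution after screening, background subtraction and denoising, and
    extracts 3D single-cell features (volumes, equivalent diameters,
    ellipsoid radii, nuclear-to-cytoplasmic ratios, micronuclei dispersion,
    reporter gating) with population statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tiff,
    jsonlite,
    yaml,
    igraph,
    mclust,
    minpack.lm,
    EBImage,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
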
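Package: symscan
Title: Approximate Symmetry Detection in Biological Images via
    Transformation Information
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies approximate rotation, reflection, translation and
    rotation-rescale symmetries of 2-D biological images and patterns with
    the Transformation Information (TI) measure, a Kullback-Leibler-type
    divergence between a strictly positive intensity field and its geometric
    transform evaluated over their overlap domain. Provides automated
    detection of symmetry axes and centres from TI curves, baseline
    asymmetry measures (the area-based Simple Indicator for bilateral
    symmetry and a landmark nearest-neighbour measure for rotations), a
    spectral fourth-order exponential-time-differencing simulator for a
    two-species Turing reaction-diffusion model on a periodic square with
    optional symmetry-breaking advection, linear-stability diagnostics, and
    a synthetic fixture generator producing images with known ground-truth
    symmetries (rosettes, bilateral blobs, pentagon landmarks, decussate
    whorls, plane waves).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    EBImage,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Software, Visualization, CellBiology
RoxygenNote: 7.3.3
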
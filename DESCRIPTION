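Package: metpipe
Title: Metabolite Identification and Two-Group Biomarker Discovery with
    Two-Dimensional Local FDR Control
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A GC-MS metabolomics pipeline covering spectral-library
    identification and two-group biomarker discovery. Identification matches
    sample mass spectra against a user-supplied library with a cosine-angle
    dissimilarity score and fits a four-layer hierarchical latent-variable
    model (presence, match, correctness, score) by an EM algorithm, yielding
    a posterior confidence measure for each library metabolite. Biomarker
    discovery tests all metabolites simultaneously with Welch t-statistics
    and controls the two-dimensional local false discovery rate over the
    (t, log standard error) plane, estimated from permutation null
    statistics, with isoline-based rejection and volcano/tornado plot data.
    Includes MSP spectrum input/output, peak merging, intensity-matrix
    normalization, kernel density diagnostics, and model-faithful simulators
    for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    jsonlite,
    mgcv,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
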
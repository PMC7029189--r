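Package: confield
Title: Three-Dimensional Connective Field Mapping of Region-to-Region
    Functional Connectivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits three-dimensional isotropic Gaussian connective fields to
    resting-state BOLD functional connectivity between a seed and a mapping
    region, and quantifies the spatial organization of the resulting maps.
    Provides Procrustes-based rank linearity with a resel-corrected binomial
    null model, a three-dimensional Kolmogorov-Smirnov convergence statistic
    with a Monte Carlo critical value, vector-field summaries, all-pairs
    parcel linearity matrices, network contrasts, thresholded topography
    graphs, nonmetric-MDS gradient decomposition, and regression of task
    contrast maps on connectivity gradients. Includes a synthetic phantom
    generator with known connectivity structure for validation, NIfTI
    input/output, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    RNifti,
    graphics,
    grDevices,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
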
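Package: mngmm
Title: Multigrid Nonlocal Gaussian Mixture Segmentation of Brain MR Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Segmentation of skull-stripped brain magnetic resonance images
    into cerebrospinal fluid, gray matter, and white matter. A Gaussian
    mixture model fitted by expectation-maximization is made robust to
    noise by nonlocal-means weighting of the class posteriors, and robust
    to intensity inhomogeneity by an adaptive multigrid decomposition of
    the brain region: grid cells are merged into patches driven by the
    fuzzy-c-means inner distance, a nonlocal Gaussian mixture model is
    fitted per patch, and per-voxel posteriors are fused across
    neighboring patches with likelihood weights. Includes a synthetic
    three-tissue phantom generator with controllable noise and bias-field
    levels, Jaccard-based evaluation, and NIfTI/PNG/TIFF input and output.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    png,
    tiff,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    e1071,
    mclust,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
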
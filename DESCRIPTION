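Package: omtapc
Title: Optimal-Mass-Transport Tensorization and Algebraic Preclassification
    for Volumetric Brain MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts irregular masked 3D brain volumes into regular cubic
    tensors by a density-weighted discrete optimal-mass-transport (OMT)
    parameterization built on a tetrahedral voxel mesh, with a tunable density
    that enlarges a designated whole-tumor region, and classifies the resulting
    tumor tensors with an algebraic preclassification model: multimode
    truncated-SVD features fed to multiview orthonormalized partial least
    squares (MvOPLS) solved as a generalized eigenvalue problem. Includes a
    deterministic synthetic phantom generator, classification and segmentation
    metrics, and an end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
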
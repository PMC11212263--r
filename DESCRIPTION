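Package: tmplkit
Title: Groupwise Diffeomorphic Brain Template Construction and
    Deformation Metrics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for building population-average brain templates by
    iterative groupwise diffeomorphic registration and for quantifying
    the deformation associated with spatial normalization.  Implements a
    stationary-velocity-field registration core (exponentiation by
    scaling and squaring, field composition, warping, multiresolution
    diffeomorphic demons), an unbiased mean-and-register template
    builder with velocity-space recentring, per-voxel displacement and
    log-Jacobian-determinant deformation maps with atlas-based region
    summaries, paired template comparisons with Bonferroni correction,
    and a synthetic 3D head-phantom population generator with known
    ground-truth warps for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    stats,
    tibble
LinkingTo:
    Rcpp
Suggests:
    ggplot2,
    jsonlite,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
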
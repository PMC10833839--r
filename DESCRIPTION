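Package: tonguemorph
Title: Soft-Organ Morphology Prediction by Symmetric Free-Form CT Registration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts the morphology of a soft organ (the tongue) from cranial
    anatomy by non-rigid registration of 3D head and neck CT volumes. Implements
    symmetric multi-resolution free-form-deformation (FFD) registration driven
    by a four-term cost (normalized cross-correlation, mid-sagittal symmetry,
    paired anatomical landmarks, bending-energy penalty), morphing of a
    reference tetrahedral finite-element tongue mesh through the recovered
    deformation, Jacobian-based mesh quality assessment, and an adaptive
    simplex stochastic-collocation uncertainty-quantification loop over the
    two most sensitive registration parameters (finest grid spacing and
    regularization weight). Includes a deterministic CT-like phantom generator
    with known ground-truth deformations for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    RNifti,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
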
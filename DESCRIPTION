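Package: morphons
Title: Diffeomorphic Morphons Deformable Image Registration
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Nonparametric deformable registration of 2D and 3D scalar
    images driven by local phase differences from quadrature (loglet)
    filter banks, with certainty-weighted field accumulation and
    normalized-convolution regularization. Displacement fields can be
    accumulated additively, compositively, or diffeomorphically through
    scaling-and-squaring exponentiation of the update field, which keeps
    the deformation invertible (positive Jacobian determinant). Includes
    classical intensity-difference (Demons) updates as a comparator,
    a coarse-to-fine multiscale driver, synthetic phantoms with known
    ground-truth diffeomorphisms, evaluation metrics (SSD, harmonic
    energy, Jacobian analysis, landmark error, mask volume change,
    mutual information), and NIfTI/MetaImage volume input and output.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
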
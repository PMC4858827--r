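Package: aneumorph
Title: Modality Sensitivity of Image-Based Intracranial Aneurysm Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies how angiographic imaging modality propagates into
    image-based models of saccular intracranial aneurysms. Generates
    synthetic aneurysm phantoms with closed-form morphological ground
    truth, renders modality-degraded image volumes emulating rotational
    angiography, CT angiography and MR angiography, reconstructs lumen
    surfaces (threshold segmentation, region growing, isosurface
    extraction, Taubin smoothing, anatomical region partition), computes
    the standard morphological parameters (size, aspect ratio, neck area,
    parent vessel diameter, size ratio, aneurysm angle), derives
    wall-shear-stress based hemodynamic statistics (AWSS, OSI, AWSSG and
    their regional summaries) from time-resolved surface vector fields,
    measures symmetric surface distances between models after rigid
    alignment, and compares modalities with paired nonparametric
    statistics and Cohen's kappa.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    igraph,
    Matrix,
    stats,
    utils,
    graphics,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
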
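Package: usdot
Title: Simulation and Two-Region Reconstruction for Ultrasound-Guided
    Time-Domain Diffuse Optical Tomography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end simulation and analysis toolkit for ultrasound-guided
    time-domain diffuse optical tomography (DOT) of breast lesions. Generates
    voxelized breast digital phantoms with embedded benign or malignant
    lesions, assigns dual-scale stochastic acoustic media and
    chromophore-based optical properties, solves the time-domain diffusion
    equation on the voxel grid for a reflectance probe with eight sources and
    eight detectors, applies instrument-response convolution and
    photon-counting Poisson noise, reconstructs lesion and bulk optical
    coefficients per wavelength with a two-region nonlinear model driven by a
    morphological prior, emulates the geometric quality of ultrasound-derived
    priors, and classifies reconstructed lesion spectra into benign and
    malignant with logistic regression, kernel support vector machines and a
    small fully connected network.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    minpack.lm,
    e1071,
    EBImage,
    yaml,
    jsonlite,
    RNifti,
    rlang,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
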
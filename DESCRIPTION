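Package: paraxtomo
Title: Paraxial Full-Wave Transmission Ultrasound Tomography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative transmission ultrasound tomography on synthetic
    phantoms: one-way paraxial (split-step Fourier) frequency-domain forward
    simulation of plane-wave insonification, frequency-hopping inverse
    scattering for speed-of-sound and attenuation maps by adjoint-state
    Polak-Ribiere nonlinear conjugate gradients, time-of-flight straight-ray
    initialization, eikonal/ray refraction-corrected reflection imaging, and
    fusion, morphological bone separation, tissue segmentation and ROI
    statistics for postprocessing. Includes phantom generators with
    bone-like high-contrast inclusions, a frequency-domain dataset
    container, NIfTI volume export and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    RNifti,
    igraph,
    EBImage,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
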
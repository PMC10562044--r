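Package: luscint
Title: Simulation and Deep Denoising of Lu-177 Planar Scintigraphy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale toolkit for studying scan-time reduction in Lu-177
    planar scintigraphy. Generates digital activity/attenuation phantoms
    (Shepp-Logan, parametric brain, Derenzo hot-rod, anthropomorphic torso),
    projects them through an analytic gamma-camera model (parallel-hole
    collimator with depth-dependent Gaussian resolution, water attenuation,
    Poisson counting), produces reduced-count images by binomial thinning,
    trains a DenseNet-style convolutional denoiser on paired sub-images, and
    quantifies fidelity with RMSE/PSNR/SSIM, Otsu-based ROI significance
    testing, and MIRD conjugate-view activity and absorbed-dose estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    tiff,
    jsonlite,
    stats,
    utils,
    tools,
    graphics,
    grDevices
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
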
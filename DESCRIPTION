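Package: boldsim
Title: Forward Simulation of BOLD MRI Signal Decay from Susceptibility Perturbers
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Forward simulator of transverse MR signal decay (BOLD-type
    contrast) arising from magnetic-susceptibility perturbers inside a tissue
    voxel. Blood vessels are modelled as infinite cylinders (2D or 3D),
    spheres, or arbitrary discretized susceptibility masks. Field offsets are
    computed analytically from the dipole closed forms or by Fourier
    convolution with the 3D dipole kernel; water diffusion is simulated either
    by Monte Carlo random walks in continuous space with permeable perturber
    walls, or deterministically by convolving the magnetization grid with a
    Gaussian or discrete-Bessel diffusion kernel. Arbitrary RF pulse trains
    (gradient-echo, spin-echo, asymmetric spin-echo) are supported, together
    with delta-R2/delta-R2' relaxation-rate analysis and Boxerman-style
    vessel-radius sweeps.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
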
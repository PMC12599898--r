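Package: ctsim
Title: Physically Grounded Thick-Slice CT Simulation for Super-Resolution Training Pairs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates thick-slice axial CT volumes from thin-slice acquisitions
    using slice-position correction in the DICOM patient coordinate system and a
    triangular slice-sensitivity weighting of thin slices, alongside three
    conventional baselines (direct downsampling, simple averaging, Gaussian
    averaging). Includes DICOM-series and NIfTI volume I/O with physical
    per-slice z-positions, analytic digital phantoms with dense-quadrature
    ground-truth thick slices, and per-slice PSNR/MSE/RMSE/SSIM fidelity
    reporting, so that realistic low-resolution/high-resolution training pairs
    for CT super-resolution can be generated and compared.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    tibble,
    jsonlite,
    stats,
    utils,
    ggplot2,
    generics,
    rlang
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
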
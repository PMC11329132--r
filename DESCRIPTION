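Package: ctthinslice
Title: Conditional-GAN Slice-Thickness Reduction and Interpolation for CT Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to reduce CT slice thickness and interpolate adjacent
    slices in one step (e.g. 3 mm to 1 mm) with conditional generative
    adversarial networks. Implements a U-Net generator with a PatchGAN
    discriminator, two training-target constructions (raw thin-slice
    regression and residual difference learning), the five-position
    slice-generation scheme (2P, 1P, C, 1N, 2N) with its thick-to-thin
    slice-location mapping, paired-volume phantom simulation for
    fully synthetic end-to-end testing, leave-one-case-out
    cross-validation, and a quantitative evaluation suite (PSNR, MSE,
    SSIM, per-slice method-winner counts, signed difference images,
    Cohen's kappa). Volumes are read and written as NIfTI-1 or as a
    minimal DICOM series.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    RNifti,
    png,
    yaml,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    e1071
Config/testthat/edition: 3
RoxygenNote: 7.3.3
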
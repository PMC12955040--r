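Package: lffuse
Title: Dual-Modality Light-Field Microscopy Simulation and Fusion Reconstruction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Wave-optics simulation of light-field microscopy (LFM) and Fourier
    light-field microscopy (FLFM) imaging, and 3D reconstruction by a four-branch
    multimodal fusion network. Includes Debye-integral point-spread-function
    computation for both modalities, angular-spectrum propagation, microlens-array
    modelling, forward projection of 3D volumes to sensor images, epipolar-plane-image
    extraction, synthetic tubulin and vessel phantom generation, a Richardson-Lucy
    deconvolution baseline, and PSNR/SSIM evaluation utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    pracma,
    tiff,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    png
Config/testthat/edition: 3
RoxygenNote: 7.3.3
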
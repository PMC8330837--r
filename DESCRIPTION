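Package: fptycho
Title: Fourier Ptychographic Reconstruction with Zernike Aberration
    Recovery and Total-Variation Regularization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and reconstruction for LED-array Fourier
    ptychographic microscopy. Provides a physics-faithful forward model
    (coherent transfer function, angle-varied illumination, Fourier-domain
    aperture cropping), a gradient-based reconstructor that alternately
    updates the high-resolution complex sample and a Zernike-parameterized
    pupil with optional total-variation regularization, and a classical
    alternating-projection/ePIE baseline with free-form pupil recovery.
    Includes a synthetic phantom generator, quantitative evaluation that
    handles the global-phase ambiguity, and multi-page TIFF + YAML
    input/output with a small command-line driver.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
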
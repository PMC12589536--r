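Package: comsli
Title: Computational Scattered Light Imaging of Fiber Orientations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis pipeline for computational scattered light imaging
    (ComSLI) of histological sections. Reads azimuthal image stacks,
    performs diffuser-based flat-field correction, extracts up to three
    in-plane fiber orientations per pixel from the periodic azimuthal
    intensity profile (Fourier low-pass filtering, circular peak detection,
    180-degree peak pairing), renders fiber orientation maps and vector
    overlays, computes multi-resolution crossing statistics, builds
    microstructure-derived fiber orientation distributions (polar
    histograms with periodic spline representations), and synthesizes an
    artificial diffusion-MRI dataset so that the orientations can be
    consumed by standard tractography tools. Includes a scattering phantom
    generator with known ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    tiff,
    RNifti,
    jsonlite,
    yaml,
    png,
    grDevices,
    graphics,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
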
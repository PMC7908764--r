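Package: poretex
Title: Pore Texture Analysis of 3D Ultrasound Volumes for Implanted
    Hernia Mesh Identification
Version: 0.1.0
Authors@R:
    person("poretex", "developers", role = c("aut", "cre"),
           email = "poretex@example.org")
Description: Texture-based identification of implanted lightweight surgical
    hernia mesh in automated 3D ultrasound (ABUS-style) volumes. Provides 2D
    and 3D (collinear-triplet) gray-level co-occurrence matrices with twelve
    Haralick-style features each, spectral fractal dimension estimation from
    radially averaged FFT power spectra, positional features (scan depth and
    hernia-sac proximity), per-feature inter-class distance ranking, a seeded
    synthetic speckle/mesh/fascia phantom generator, and an end-to-end
    feature-extraction pipeline with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
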
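Package: dcsflow
Title: Diffuse Correlation Spectroscopy Forward Models, Correlators, Noise and
    Laser-Safety Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for diffuse correlation spectroscopy (DCS) blood-flow
    analysis: closed-form field and intensity autocorrelation models for a
    semi-infinite turbid medium with point or finite-disk illumination,
    multi-tau autocorrelation of photon-count streams, an analytic
    photon-counting noise model with the derived signal-to-noise ratio,
    Brownian-diffusion (flow index) fitting with batch time courses,
    limiting-aperture maximum-permissible-exposure analysis of measured or
    synthetic beam profiles, and seeded generators for speckle photon streams,
    noisy correlation curves, beam images and cuff-occlusion flow protocols.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    pracma,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
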
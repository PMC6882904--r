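Package: gatednirs
Title: Time-Gated Non-Contact Diffuse Optical Brain Imaging Toolkit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis toolkit for nanosecond time-gated
    wide-field near-infrared imaging of deep tissue. Provides Monte Carlo
    photon transport in layered head models with time-resolved detection
    and partial-pathlength tallies, square-pulse superimposition and
    electronic-shutter gating of temporal point spread functions, the
    per-pixel photon and electron budget of a gated image sensor,
    synthesis of optical-density-change images of deep absorbing
    inclusions with a sampling-pitch binning study, and the
    dual-wavelength haemodynamic signal-processing chain (row
    de-interleaving, modified Beer-Lambert inversion, zero-phase
    band-pass filtering, normalized trial averaging and power spectra),
    together with a synthetic-data generator for block-task recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    signal,
    yaml,
    tiff,
    png
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
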
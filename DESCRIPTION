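Package: ls2wmv
Title: Multivariate Locally Stationary 2D Wavelet Processes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Modelling framework for multivariate locally stationary
    two-dimensional wavelet (LS2Wmv) random fields, aimed at colour
    texture analysis. Provides simulation of multichannel nonstationary
    fields with prescribed local wavelet spectra and cross-channel
    coherence, consistent estimation of local wavelet auto- and
    cross-spectra and coherence (non-decimated wavelet periodograms,
    Nadaraya-Watson smoothing, bias correction by the inverse
    autocorrelation-wavelet inner-product matrix), and a nearest-centroid
    linear-discriminant colour-texture classifier built on the resulting
    spectral features.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    tools,
    grDevices,
    graphics,
    jsonlite,
    yaml,
    png,
    tiff
Suggests:
    testthat (>= 3.0.0),
    MASS
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
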
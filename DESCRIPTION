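Package: vinespec
Title: On-the-Go NIR Chemometrics for Grapevine Water Status
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for estimating grapevine stem water potential from
    vehicle-mounted near-infrared reflectance spectra. Simulates
    georeferenced on-the-go spectral streams over a blocked irrigation
    trial, replays the automated acquisition workflow (dark/white
    referencing, leaf-signature capture, cosine-similarity filtering),
    applies standard normal variate and Savitzky-Golay derivative
    preprocessing, fits partial least squares regression by NIPALS with
    venetian-blind cross-validation and VIP wavelength importance, and
    interpolates predictions into classed vineyard water-status maps by
    thin-plate splines.
License: MIT + file LICENSE
Depends: R (>= 4.0)
Imports: stats, utils, graphics, grDevices, jsonlite
Encoding: UTF-8
Suggests: testthat (>= 3.0.0), signal, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
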
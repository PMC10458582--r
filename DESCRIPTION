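Package: fpsense
Title: Fiber-Optic Fabry-Perot Cavity-Length Sensing and Palatal
    Expansion Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Toolkit for low-finesse fiber-optic Fabry-Perot (F-P)
    displacement sensors of the kind used to monitor midpalatal suture
    opening during rapid palatal expansion. Forward-models two-beam
    reflected interference spectra, recovers absolute cavity length by
    fringe-order demodulation of interference peak wavelengths, tracks
    cavity length over spectrum sequences, detects screw-activation
    steps, and derives opening distances and the suture expansion angle
    from a two-sensor arrangement. Includes a ground-truthed synthetic
    experiment generator (activation staircases, interrogator wavelength
    jitter, thermal drift, translation-stage calibration scenarios),
    plain-text file formats, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
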
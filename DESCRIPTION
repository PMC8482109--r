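Package: hpmri
Title: Metabolite-Specific Hyperpolarized Carbon-13 MRI Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale virtual experiment for metabolite-specific imaging of
    hyperpolarized [1-13C]pyruvate and [1-13C]lactate at 4.7 T. Designs
    spectral-spatial radiofrequency (SSRF) excitation pulses on flyback
    gradient trains, verifies them with an independent Bloch-equation
    simulator and an emulated profile-measurement sequence, acquires dynamic
    flyback echo-planar images and chemical shift imaging (CSI) data from a
    synthetic rat-abdomen phantom with a hyperpolarized magnetization budget,
    reconstructs metabolite image series with fractional chemical-shift
    displacement correction, and implements an automated real-time
    center-frequency calibration procedure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    yaml,
    RNifti,
    stats,
    utils,
    grDevices,
    graphics
Suggests: testthat (>= 3.0.0), withr, optparse, knitr, rmarkdown
Config/testthat/edition: 3
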
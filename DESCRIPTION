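Package: retiwave
Title: Retinal Broadband-NIRS Slow-Wave Oscillation and Wavelet Semblance
    Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for non-invasive retinal metabolism
    measurements from broadband near-infrared spectroscopy (bNIRS).
    Converts reflected-intensity spectra to chromophore concentration
    changes (oxidized cytochrome-c-oxidase, oxy- and deoxy-hemoglobin)
    via a multiwavelength modified Beer-Lambert least-squares fit,
    isolates slow-wave oscillations (zero-phase low-pass filtering and
    polynomial detrending), quantifies oscillation period and regularity
    from the amplitude spectrum, and measures mitochondria-hemodynamics
    phase coupling with complex-Morlet wavelet semblance. Includes a
    synthetic cohort generator with known ground truth and non-parametric
    group statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
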
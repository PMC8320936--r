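Package: doctvib
Title: Phase-Resolved Doppler Optical Coherence Tomography Vibrometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of phase-resolved spectral-domain Doppler
    optical coherence tomography (DOCT) for vibrometry of middle-ear structures.
    Provides a synthetic spectrometer interferogram simulator of a layered,
    sinusoidally vibrating phantom (tympanic membrane and malleus stand-ins)
    with finite-exposure fringe washout, nonuniform-in-wavenumber sampling and
    seeded noise; the spectral reconstruction chain (background subtraction,
    k-linearization, apodization, FFT, log scaling); Kasai autocorrelation
    Doppler phase estimation with spatial averaging, velocity conversion and
    Nyquist/aliasing utilities; and ROI-based frequency-response analysis with
    control subtraction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ggplot2,
    grDevices,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
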
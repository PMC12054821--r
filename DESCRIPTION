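Package: cryodecay
Title: Dose-Dependent Information Loss Analysis for Low-Temperature Cryo-EM
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis suite for quantifying dose-dependent information loss in
    electron cryomicroscopy at liquid-helium versus liquid-nitrogen specimen
    temperatures. Provides metrics of beam-induced particle and foil motion from
    coordinate tracks, Voigt peak fitting of electron diffraction radial profiles
    and electron energy-loss spectra with a plasmon-energy/density model, a
    per-frame B-factor decay pipeline built on half-set Fourier shell
    correlations, pseudo-Brownian motion and spatial-coherence (charge
    fluctuation) model fits, instrument-physics calibrations (coincidence loss,
    four-point-probe sheet resistance, electron flux, ice-thickness inversion),
    and seeded synthetic-data generators that emulate every input so the full
    pipeline is testable without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    minpack.lm,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
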
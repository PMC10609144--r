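Package: hkbright
Title: Helmholtz-Kohlrausch Corrected Brightness Prediction for Wide-Gamut Displays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the perceived brightness of chromatic stimuli on
    wide-gamut (laser) displays, where the Helmholtz-Kohlrausch effect makes
    saturated colors look brighter than achromatic light of equal luminance.
    Implements the CAM16 forward color appearance model, the Nayatani
    variable-achromatic-color (VAC) and variable-chromatic-color (VCC)
    equivalent-luminance models, a Hellwig-form chroma correction to CAM16
    lightness, and a CAM16-based brightness model with an explicit
    Helmholtz-Kohlrausch compensation term. Also provides the coefficient of
    variation (CV) agreement statistic used in brightness-matching
    psychophysics, multistart nonlinear refitting of the compensation
    parameters, chromaticity-diagram gamut-area and coverage geometry for
    display primaries against the visible gamut and the BT.2020 standard, and
    a synthetic brightness-matching experiment generator with per-observer
    noise.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
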
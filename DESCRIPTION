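Package: whiskbroom
Title: Whisk-Broom Hyperspectral Imaging: Simulation, Calibration and
    Radiometry
Version: 0.1.0
Authors@R:
    person("Packaged", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for whisk-broom (gimbal-scanned point-spectrometer)
    hyperspectral imaging of light environments, aimed at low-light and
    artificial-light-at-night work. Provides a forward model of a 288-photosite
    micro-spectrometer on a pan/tilt gimbal (dark current, sensor
    non-linearity, shot-like noise, saturation), the acquisition logic that
    exposes every pixel independently on an octave integration-time ladder
    with scheduled dark frames and Mercator pole skipping, calibration
    procedures (linearisation-coefficient fitting from an integration-time
    ladder and spectral-sensitivity estimation from a white-standard scan),
    and radiometric rendering: absolute spectral radiance, relative
    reflectance, sRGB/extended-range/saturation/NDVI previews and quantal
    cone-catch images, plus plain-text scan file I/O and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
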
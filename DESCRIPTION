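Package: photopet
Title: Analysis of Photonuclear Induced Positron Activity from Dynamic PET
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the positron activity induced in tissue by
    high-energy (>15 MeV) photon radiotherapy, as measured with a dynamic PET
    acquisition started shortly after the end of irradiation. Fits a
    constrained multi-exponential decay model to volume-of-interest
    time-activity curves, in a fixed-half-life regime (11C, 15O, 13N held at
    their physical half-lives) and a free-half-life regime, with 95%
    confidence intervals; maps the fitted relative count-rate fractions to a
    tissue elemental composition and compares it against hydrogen-omitted
    ICRU reference compositions. Includes NIfTI-1 volume-of-interest
    extraction, a time-activity-curve CSV dialect, a synthetic-data generator
    with Poisson counting noise emulating the low-count post-treatment
    regime, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    graphics,
    jsonlite,
    minpack.lm,
    pracma,
    RNifti,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
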
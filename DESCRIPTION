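Package: smloop
Title: Single-Molecule Analysis of Transcription-Factor-Mediated DNA Looping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for two-color single-molecule localization
    measurements of DNA looping in live bacteria: synthetic movie and
    trajectory generation, sub-pixel Gaussian spot fitting with
    residual-permutation error estimates, projective two-channel
    registration, displacement-distance distribution statistics,
    mixture-based looping-frequency estimation, vector autocorrelation
    kinetics, worm-like-chain apparent-distance simulation, smFISH
    transcript counting, and a statistical-thermodynamic model of lambda
    repressor (CI) autoregulation with octamer- and tetramer-mediated
    looping between the O_L and O_R operators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tiff,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
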
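Package: specfg
Title: Functional Group Prediction from FTIR and EI-MS Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Database-free identification of the functional groups present in a
    compound (or mixture) from its infrared and electron-ionisation mass
    spectra. Parses JCAMP-DX records, standardises spectra onto fixed
    wavenumber and unit-mass bin grids, assigns multi-label ground truth by
    SMARTS substructure matching, and trains a multi-label feed-forward neural
    network with per-group decision thresholds. Ships molecule-level
    evaluation metrics (molecular F1 and molecular perfection rate), an
    accuracy-matched synthetic baseline, a spectral autoencoder variant,
    guided-backpropagation saliency profiles, and a synthetic spectrum
    generator for end-to-end testing without proprietary reference data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ChemmineOB,
    jsonlite,
    ranger,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
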
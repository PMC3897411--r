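Package: emsaquant
Title: Densitometric Quantification of Electrophoretic Mobility Shift Assays
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies electrophoretic bands in scanned autoradiographs,
    stained gels and phosphorimages, correcting the non-linear saturation of
    autoradiographic film via a calibrated step tablet, and determines
    stepwise protein-DNA equilibrium constants from electrophoretic mobility
    shift assays (EMSAs) with a full per-lane error budget (non-uniform
    background, dissociation smear, technical error), lane averaging,
    reference normalization, and cooperative binding constants for two-site
    constructs. Includes a physical simulator of the dissociation smear
    produced during electrophoresis and a synthetic-EMSA generator with
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports: methods, stats, utils, grDevices, tiff, png, yaml, jsonlite
Suggests: testthat (>= 3.0.0), readxl, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
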
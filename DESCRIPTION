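Package: qmrilesion
Title: Multicontrast Quantitative MRI Lesion Classification and Clinical
    Modelling
Version: 0.1.0
Authors@R:
    person("Lesion", "Mapper", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for multicontrast quantitative MRI of focal
    brain lesions. Computes region-conditional healthy-control reference
    statistics for T1, T2 and T2* relaxation times and the magnetization
    transfer ratio, derives per-lesion z-scores against the matching lobe and
    tissue compartment, converts z-score vectors into tri-state combination
    signatures with pathology-group assignment, summarizes mean lesion volume
    per combination, and relates per-subject combination volumes to clinical
    scores through Box-Cox transformation, backward stepwise linear modelling,
    Bonferroni correction and leave-one-out cross-validation. Includes a
    synthetic multicontrast phantom generator with known ground truth, minimal
    NIfTI-1 input/output, and a subcommand-style command line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
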
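Package: cochleaging
Title: Transcriptomic and Biophysical Analysis of Aging Cochlear Hair Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying age-related change in cochlear hair cells
    across four experimental modalities: bulk RNA-seq of isolated inner and
    outer hair cells (RPKM background filtering, fold-change/FDR differential
    expression, ranked gene-set comparisons and over-representation tests),
    dual-sine membrane-capacitance estimation with two-state Boltzmann
    nonlinear-capacitance fitting and charge-density normalization, outer
    hair cell axial stiffness from calibrated-fiber motion, and
    cochleogram/fluorescence quantification with the associated group
    statistics (Student's t, Holm-Sidak). A synthetic-data module simulates
    every input with known ground truth, so each stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
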
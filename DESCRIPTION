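Package: diffclone
Title: Differential Abundance Testing for T-Cell Clones in Immunosequencing Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects T-cell clones whose frequencies differ between two
    TCR-beta immunosequencing samples. Implements the exact binomial test of
    clone frequency change and a beta-binomial extension whose dispersion is
    calibrated from paired same-subject samples, capturing time-dependent
    biological variability beyond multinomial sampling noise. Includes
    Benjamini-Hochberg control of the false discovery rate over the tested
    clone set, annotation of expanded clones against a reference (tumour)
    repertoire, readers for immunoSEQ-style and generic clone tables, and a
    synthetic-repertoire simulator for false-positive-rate and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
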
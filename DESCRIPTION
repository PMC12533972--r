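Package: myoregen
Title: Cell Population Dynamics of Skeletal Muscle Regeneration
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A nine-population ordinary-differential-equation model of the
    cellular response to acute skeletal muscle injury (damaged myonuclei,
    neutrophils, monocytes, M1 and M2 macrophages, and the satellite-cell
    lineage), with tools to calibrate single-cell-derived cell-type
    proportions to absolute densities per cubic millimeter, fit the rate
    constants by bound-constrained Nelder-Mead minimization of a normalized
    absolute-deviation error, run local one-at-a-time parameter sensitivity
    analysis, and generate replicate-structured synthetic count tables for
    end-to-end validation and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
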
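Package: pieacq
Title: Precursor Ion Exclusion Acquisition Simulation and Exclusion-List Tools
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for precursor ion exclusion (PIE) workflows in shotgun
    proteomics. Implements an exclusion-list engine (parsing of tabular
    exclusion exports, ppm/retention-time clustering, cross-run merging,
    capacity capping, and instrument-import CSV export) together with an
    in-silico LC-MS/MS data-dependent acquisition simulator: synthetic
    two-channel TMT-labeled tryptic mixtures, top-N precursor selection with
    dynamic exclusion, stochastic identification with target-decoy FDR
    filtering, reporter-ion ratio quantification, and comparison statistics
    (Venn counts, percent increase, log2-ratio regression) between standard
    DDA replicates and exclusion-list-based iterative acquisition.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    Biostrings,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
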
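Package: corerank
Title: Ranking Core Transcriptional Regulators from Periodic Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores time-series transcript abundance profiles for periodicity
    at a specified period and for regulation strength (variability about the
    mean), attaches resampling-based empirical p-values and a tie-aware
    JTK-CYCLE rhythmicity p-value, combines them into the DL, DL x JTK and
    PerReg ranking metrics, and evaluates how well each ranking places core
    transcriptional regulators (cell-cycle or circadian clock genes) above
    non-core genes via tie-aware precision-recall curves, average precision
    and recall among the top candidates. Includes a synthetic periodic
    transcriptome generator with labelled core, output and background genes
    for benchmarking the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
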
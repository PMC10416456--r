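Package: m6adyn
Title: Quantitative m6A Dynamics from Multi-Stage MeRIP-seq Count Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies N6-methyladenosine (m6A) levels from paired
    immunoprecipitation (IP) and input read-count matrices over a four-stage
    cardiomyocyte differentiation time course (D0, D2, D5, D15), classifies
    per-peak m6A dynamics (differential peaks, modified calls, origin stage,
    change-count classes, trajectory clusters), discovers candidate target
    genes of m6A writers and erasers by correlation-extreme intersection, and
    integrates gene-level chromatin accessibility through a five-category
    co-dynamics classification. Ships a negative-binomial study simulator
    with planted ground truth so the whole pipeline is testable without
    sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    purrr,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    withr,
    stats,
    utils,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
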
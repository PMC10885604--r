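Package: utrstruct
Title: 3' UTR Structurome Analysis from DMS Probing Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify RNA secondary structure of 3' untranslated
    regions from dimethyl sulfate (DMS) mutational-profiling data and to
    relate that structure to transcript expression and stability. Converts
    treated/untreated per-base mismatch pileups into normalized DMS
    reactivities, scores structural heterogeneity with a sliding-window
    Gini index, builds meta-gene stop-codon profiles, classifies genes into
    high- and low-Gini deciles, and tests the association of 3' UTR
    structure with expression (RPKM) and half-life, including confounder
    stratification, G-quadruplex motif prediction, and exponential
    decay-curve fitting. A seeded synthetic-data generator emulates
    structure-dependent DMS probing so the whole pipeline is testable
    without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    rtracklayer,
    GenomicRanges,
    BiocGenerics,
    S4Vectors,
    withr,
    optparse
Config/testthat/edition: 3
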
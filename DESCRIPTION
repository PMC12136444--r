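Package: ampliclust
Title: UID-Consensus Amplicon Sequencing Simulation and Low-Frequency Variant Calling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for unique-identifier (UID) based multiplex amplicon sequencing of
    cell-free DNA. Implements primer-pair screening (nearest-neighbor melting
    temperature, GC windows, positional bias, cross-dimer scans), a seedable
    simulator of the full library genealogy (UID-tagging PCR, index and final
    amplification, off-target byproducts, hybrid capture, paired-end sequencing),
    read extraction and amplicon alignment, peer-to-peer UID-pair graph clustering
    with genealogy-bound filters, cluster-consensus variant calling for variant
    allele fractions at and below 1 percent, and an evaluation layer (on-target
    ratio, enrichment, uniformity, sensitivity/specificity, codon-level
    specificity, tube downsampling).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    stringr,
    rlang,
    data.table,
    ggplot2,
    generics,
    yaml,
    stats,
    utils,
    Biostrings,
    Rsamtools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
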
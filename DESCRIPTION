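Package: famscape
Title: Comparative Genomics of Plant Gene Families Across Multiple Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for family-scale comparative genomics
    across plant genomes: HMM-hit based family identification and positional
    renaming, exon-intron structure metrics, alignment trimming and
    neighbor-joining subfamily assignment, reciprocal-best-hit orthogroup
    construction with conserved/variable/rare classification, Nei-Gojobori
    (1986) Ka/Ks estimation with Jukes-Cantor correction and hierarchical
    aggregation, collinear-block detection and duplication-mode classification,
    promoter cis-element scanning with functional-class profiling, and
    stress-expression screening (FPKM, log2 fold change, 2^-ddCt qPCR). Ships a
    synthetic multi-species genome generator with planted ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
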
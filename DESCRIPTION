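Package: viewpointr
Title: Viewpoint-Based 4C-seq Interaction Quantitation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested, reusable pipeline for circularised chromosome
    conformation capture sequencing (4C-seq) viewpoint analysis:
    in-silico restriction digestion, inline-barcode demultiplexing,
    bait trimming, removal of undigested and self-ligation reads,
    unique fragment assignment, fixed 10 kb and adaptive read-count
    windowed quantitation, cross-library normalisation, and
    differential (subtraction) interaction tracks with bedGraph
    output. Includes a seeded synthetic-data generator (genome,
    restriction fragments, distance-decay contact profiles with
    planted enhancer fold changes, structured reads) so every stage
    is verifiable without raw sequencing data, plus qPCR arithmetic
    for standard-curve quantitation, ChIP percent-input,
    3C interaction frequencies and reference-normalised RT-qPCR
    fold changes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    withr
Suggests:
    Rsamtools,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
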
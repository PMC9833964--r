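Package: silicomate
Title: In Silico Mate-Pair Libraries and Conserved-Pair Filtering for
    Reference-Guided Scaffolding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates in silico mate-pair libraries from a read-backed
    consensus against a repeat-masked reference genome, retains only pairs
    whose placement on one or more additional reference genomes preserves
    insert size (within a configurable tolerance, default 20 percent) and
    orientation, simulates ancient-DNA-like single-end reads, ranks
    candidate reference genomes from whole-assembly alignments, and
    evaluates scaffold sets with contiguity statistics and a truth-based
    misjoin counter. Includes a seeded synthetic-data generator (genomes
    with soft-masked repeats, diverged references with SNPs, indels,
    inversions and translocations, paired-end reads, and exact
    truth-coordinate alignments) so the whole pipeline is testable at desk
    scale without external aligners or downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    dplyr,
    ggplot2,
    generics,
    purrr,
    readr,
    rlang,
    stringr,
    stringi,
    tibble,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
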
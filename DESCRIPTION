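Package: mitorder
Title: Comparative Mitogenome Architecture, Gene Order and Nucleotide Skew Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative analysis of annotated animal mitochondrial
    genomes, developed around springtail (Collembola) mitogenomics. Reads
    GenBank flat files or FASTA plus a feature table, normalizes heterogeneous
    gene naming to a canonical 37-gene vocabulary, summarizes genome
    architecture (start/stop codon classes, intergenic spacers, gene overlaps,
    base composition), extracts circular signed gene orders, detects
    rearrangements (translocations, inversions, deletions) against the
    ancestral Pancrustacea arrangement, classifies genomes into named
    gene-order models, and computes strand- and codon-position-partitioned
    AT/CG skews for two-fold and four-fold degenerate sites under the
    invertebrate mitochondrial genetic code, with interquartile-range outlier
    detection. A seeded synthetic-mitogenome generator produces annotated
    fixtures with known gene order, composition and architecture so every
    stage can be exercised without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    seqinr,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
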
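Package: splitsv
Title: User-Guided Structural Variant Detection from Long-Read Split Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects, classifies and annotates large genomic rearrangements
    (deletions, insertions, inversions, tandem duplications, translocations,
    ring chromosomes and complex insertion-deletion events) from long-read
    alignments in indexed BAM files. Split reads are reconstructed from
    primary and SA-tag-linked supplementary alignments, junction ends are
    clustered into supported breakpoints, split-read signatures are matched
    against the expected patterns for each rearrangement class, and consensus
    breakpoint coordinates are reported in an HGVS-like notation together
    with BEDPE/VCF/TSV exports. Large indels encoded as gapped (CIGAR I/D)
    alignments are called through a parallel path with median aggregation
    across reads. A deterministic simulator applies specified rearrangements
    to a reference, emits tiled faux reads with alternating orientations, and
    writes analytically exact truth BAMs, so the whole pipeline is testable
    without an external aligner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    stringr,
    readr,
    jsonlite,
    generics,
    ggplot2,
    Rsamtools,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
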
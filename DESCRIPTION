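Package: circamp
Title: Reconstruction of Circular Extrachromosomal Amplicons from
    Short-Read Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Reconstructs the structure of highly amplified circular
    extrachromosomal DNA elements (double minutes) in tumor genomes from
    paired tumor/normal short-read sequencing. Selects highly amplified
    copy-number segments from the tail of the log2 tumor/normal coverage
    ratio distribution, collects soft-clipped, discordant-pair and
    bridging-discordant structural-variant evidence around segment
    boundaries, builds a bidirected boundary graph and enumerates its
    simple cycles as candidate circular amplicons, estimates per-amplicon
    copy number from germline SNV allele ratios, validates junctions and
    multi-segment paths with linked-read barcode sharing, and compares
    amplicon complements across longitudinal (e.g. diagnosis and relapse)
    samples. A fully synthetic-data simulator generates ground-truthed
    references, alignments, SNV tables and linked-read data so that every
    pipeline stage can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicAlignments,
    IRanges,
    Rsamtools,
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    pracma,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
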
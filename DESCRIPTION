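Package: vcshard
Title: Region-Sharded Pre-Processing and Scatter-Gather Variant Calling
    for Short-Read Alignments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Desk-scale implementation of a region-sharded variant-calling
    pre-processing architecture: paired FASTQ chunking, a columnar
    key-value model of aligned reads, static load balancing of a genome
    into contiguous regions, per-region coordinate sorting, Picard-style
    duplicate marking for paired- and single-end reads written from
    scratch, region-sharded BAM emission, orchestration of pluggable
    per-region variant callers, and merging of per-region VCFs into one.
    Ships a synthetic-data generator (reference, aligned reads with
    soft clips and injected PCR-duplicate groups, ground truth) so every
    stage is testable without downloads or an aligner.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Rsamtools,
    Biostrings,
    jsonlite,
    parallel,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
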
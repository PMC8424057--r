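---
title: "Region-sharded pre-processing and duplicate marking: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Region-sharded pre-processing and duplicate marking: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vcshard)
```

## The problem and the architecture

Short-read variant calling spends much of its wall time in pre-processing:
aligning reads, sorting them by coordinate, and marking PCR duplicates
before a caller sees the data. These stages parallelize naturally if the
genome is cut into contiguous regions that can be processed independently
and merged at the end — a scatter-gather layout in which a region, not a
file, is the unit of work.

`vcshard` implements that layout at desk scale. The stages are:

1. **FASTQ chunking** — paired FASTQ inputs are split into a configurable
   number of record-synchronized chunks so each chunk can be aligned
   independently (alignment itself is an external, optional command).
2. **Key-value read model** — each alignment is held as a
   `<POS : SAM-line>` pair with the contig name carried alongside, stored
   in a columnar batch per region (integer position column, string SAM
   column, string contig column). The SAM text is the canonical value, so
   every transformation is lossless by construction.
3. **Static load balancing** — each contig is cut into
   `max(1, round(length / target))` near-equal spans, with a 47 Mb default
   target.
4. **Per-region coordinate sorting** and **duplicate marking**.
5. **Region-sharded BAM emission**, one indexed shard per region.
6. **Per-region variant calling** through a pluggable command template, and
   **VCF merging** into one file.

## Static load balancing

The region count rule is `max(1, round(length / target_size))` per contig,
with `target_size = 47,000,000` bp by default; the contig is then divided
into that many contiguous spans whose lengths differ by at most one base
(the first spans absorb the remainder). Over the 25 GRCh37 primary contigs
this yields 65 regions with a mean span of 47.6 Mb — inside the 40–50 Mb
band the design aims for — which is what the packaged test suite asserts:

```{r regions}
tab <- build_regions(grch37_contigs())
nrow(tab$regions)
mean(tab$regions$end - tab$regions$start + 1) / 1e6
```

Region spans are 1-based inclusive, matching SAM `POS` semantics; BED
export converts explicitly to 0-based half-open. Reads are assigned to
regions by their own `POS` only. Reads that are unmapped, or on contigs
absent from the table, go to an *unplaced* pseudo-shard and never enter
sorting keys or duplicate marking.

## Sorting

Within a region, records are ordered by non-decreasing `POS` with ties
broken by `(qname, flag)` ascending. The tie-break makes the sort a pure
function of content: the output is identical for any input permutation and
any worker count, which the suite checks directly. Concatenating the
per-region outputs in table order yields a globally coordinate-sorted
stream because regions tile each contig.

## Duplicate marking

The algorithm follows the Picard MarkDuplicates model:

* **Unclipped 5′ coordinate.** For a forward-strand read the grouping
  coordinate is `POS − leading_clip`; for a reverse-strand read it is
  `POS + ref_span − 1 + trailing_clip`, where `ref_span` sums the
  reference-consuming CIGAR operations (M/D/N/=/X) and clips sum soft and
  hard clipping at the respective end. This undoes the aligner's clipping
  so that differently clipped copies of one fragment still collide.
* **Keys.** A *pair* key is (library, end1, end2, orientation) with the
  two (contig, unclipped 5′, strand) ends in canonical order — smaller end
  first by (contig order, coordinate, strand). A *fragment* key (unpaired
  read or mate unmapped) is (library, contig, unclipped 5′, strand). The
  library comes from the `RG` tag resolved through the header's `@RG LB`
  field, with a deterministic `"unknown"` fallback.
* **Selection.** Within a key group the candidate with the highest score
  survives; the score is the sum of base qualities ≥ 15 over both mates.
  A fragment whose end coincides with any pair end is flagged
  unconditionally (a paired observation always outranks a single-end one);
  fragment-only groups keep their own arg-max. All ties are broken by
  ascending read name.
* **Exclusions.** Secondary (0x100), supplementary (0x800) and unmapped
  (0x4) records never form candidates, and records with a `*` CIGAR pass
  through unmarked. Records are flagged (`FLAG |= 0x400`), never dropped;
  only the FLAG field changes, which keeps marking byte-conservative.

### Region routing

Duplicate groups can span a region boundary (mate batches live where their
own `POS` falls). Each candidate is therefore processed in the region
containing its smaller canonical end. Since all members of one duplicate
group share both end coordinates by definition, every group is complete in
exactly one routing region, and per-region marking provably equals global
marking; decisions are then reconciled back to each record's storage region
by read name. When a mate record is not at hand, its unclipped end is
derived from the `MC` tag (mate CIGAR); without `MC`, `PNEXT` is used
clip-unaware and counted in a per-run diagnostic.

These choices give three properties the suite asserts: *idempotence* (the
0x400 bit is ignored when grouping, so re-marking changes nothing),
*permutation invariance* (content-based tie-breaks), and exact agreement
with an independent brute-force oracle that hashes all candidates by key
and keeps the arg-max, with no sorting, batching or routing.

Optical-duplicate detection (tile/x/y parsing) is deliberately not
implemented; all duplicates are treated as PCR duplicates. Base-quality
recalibration is out of scope — the intended downstream callers do not
require it.

## Shards, callers, merging

Each region's sorted, marked batch is written as an indexed BAM shard whose
header carries *all* `@SQ` lines of the reference, so any caller accepts
it. Callers plug in through a command template with `{bam}`, `{ref}`,
`{region_bed}`, `{vcf}` (each exactly once) and optionally `{threads}`;
two templates matching common callers ship with the package, and the test
harness uses a stub shell script. Failures are isolated per region and
recorded in the manifest; re-running the call stage touches only pending or
failed regions.

Merging takes the header from the first input (contig lines are verified
consistent), orders records by (contig order, POS, REF, ALT) and, with
zero padding, conserves the summed record count. Padding is off by default
— regions are split hard at their boundaries. When `pad > 0` is used for
callers sensitive to edge truncation, the merge restores partition
semantics by span-filtering each input to its unpadded region and dropping
exact duplicates, equivalent to naive concatenate + sort + exact-dedup.
gVCF inputs are concatenated without span filtering because
reference-block semantics differ across block boundaries.

## The synthetic-data generator

The generator makes every stage testable with no downloads and no aligner:

* a seeded uniform-base reference (any fixed seed gives byte-identical
  FASTA);
* paired fragments placed uniformly (contigs weighted by length), insert
  sizes normal(300, 30) truncated to `[read_len, contig length]` by
  rejection, read length 100, fragment orientation random;
* a `dup_rate` (default 0.1) fraction of fragments seeds PCR-duplicate
  groups whose sizes follow a truncated geometric distribution (p = 0.5,
  maximum 6) — small groups dominate real PCR duplication, and any
  distribution exercises the same code paths;
* group members copy the seed's coordinates and strands but redraw base
  qualities, drawn i.i.d. per base from {10, 20, 30, 35, 40} with
  probabilities {.05, .15, .40, .25, .15}; scores are then almost surely
  distinct (exercising the tie-free path; degenerate quality distributions
  exercise the tie-breaks), and the ≥ 15 threshold is hit by real mass at
  Q10;
* with probability `clip_prob` (default 0.1) a read receives a 5′ soft
  clip (1–10 bases) with `POS` adjusted so its unclipped 5′ coordinate is
  unchanged — the keystone invariant that `unclipped_5prime()` of every
  emitted record equals the truth table's coordinates, which is what makes
  duplicate-recovery tests exact rather than statistical;
* the truth table marks, per group, the member duplicate marking is
  expected to keep: the highest-scoring pair (smallest name on ties).

What the generator does **not** emulate: sequencing errors and indels
(reads are exact reference substrings; alignment is bypassed), optical
duplicate geometry, chimeric/supplementary alignments, coverage gradients
and GC bias, and deep-coverage titrations. Passing tests therefore
demonstrate the algorithmic contracts — key construction, selection,
routing, conservation, determinism — not robustness to aligner noise.

## Numerical and degenerate-input choices

* Positions and region spans fit in 32-bit integers (the largest human
  contig is ~249 Mb).
* An unclipped 5′ coordinate may fall outside `[1, contig length]` after
  clip adjustment; it is clamped only for region-routing lookups, never in
  keys.
* A CIGAR of only clip operations contributes a zero reference span;
  `*` CIGARs exclude the read from keys.
* Empty regions produce valid, indexed, empty shards; empty batches sort
  and seal without special cases.
* More requested FASTQ chunks than records caps the plan at one record per
  chunk with a warning; remainder records go to the lowest-index chunks.

## Problem sizes in the shipped tests

The suite runs simulations of 100–400 read pairs over a two-contig 100 kb
reference partitioned into four regions, including fifty seeded replicates
of the oracle-equivalence check; these sizes give exact set-level
assertions (not sampling-based approximations) while keeping the whole
suite under a minute on a laptop.

## Known limitations

* Single-sample, short-read, germline orientation; no multi-sample joint
  calling.
* Duplicate marking flags primary records only (no 0x400 propagation to
  secondary/supplementary records).
* The in-process columnar store holds a run in memory; the architecture's
  contracts (per-region independence, worker-count invariance) are what is
  implemented, not a distributed engine.
* BAM/CRAM binary parsing is delegated to the samtools-based I/O layer;
  CRAM is not supported.
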
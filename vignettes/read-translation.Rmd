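---
title: "Interpreting and translating structured sequencing reads"
author: "seqBabel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interpreting and translating structured sequencing reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seqBabel)
```

## The problem

Highly multiplexed sequencing assays encode their information in the
*structure* of the read: a droplet scRNA-seq read carries a cell identifier
and a UMI at fixed offsets of read 1 and cDNA on read 2; split-pool assays
spread a combinatorial cell identity over several index reads; well-array
screens tag each well with row, column and plate barcodes; long reads
embed barcodes between constant flanking motifs at variable offsets.
Analysis tools are usually written against exactly one such layout, so
conceptually identical experiments cannot share pipelines.

seqBabel decouples the two concerns. A plain-text *process configuration*
declares where the information-bearing segments sit and how they relate;
the package extracts and error-corrects them, converts them into a
compact numerical *value space*, and can re-emit the same information as
FASTQ of any other declared structure, so that a tool built for the
destination layout can analyze reads born in the source layout.

## The pipeline

1. **Segment identification.** Each declared source structure is compiled
   into a matcher. Fixed-span segments use 0-based half-open coordinates;
   anchored segments are located by their neighboring constant motifs under
   a fuzzy-matching policy in which the `innerExact` bases adjacent to the
   segment must match exactly while up to `outerMaxMismatch` substitutions
   are tolerated in the rest of the motif (defaults 3 and 2 for 20-base
   flanks, i.e. a 3-base exact inner edge and at most two mismatches over
   the remaining 17 bases). Several alternative structures may be declared
   over one input pool; the **first** declared structure that fully matches
   claims the read. This precedence is deliberate: it is deterministic and
   user-controllable through declaration order, which matters for pooled
   libraries whose structures share prefixes.
2. **Quality filtering.** A read is dropped when any governed segment has
   an average Phred score below `minAvgQ` (default 20) or a minimum
   per-base score below `minBaseQ` (default 10). The thresholds are
   exclusive — a segment at exactly the threshold passes — and the whole
   read is dropped rather than the offending segment alone, because a
   record must be complete to be translated. Averages are arithmetic means
   of integer Phred scores, not error-probability means: the simplest
   reading of "average quality", and monotone in either convention at the
   scales involved.
3. **Error correction.** Per-chunk tallies of unique segment sequences are
   merged and a correction table is built once, so the result is provably
   independent of how the input was chunked. Three built-in methods:
   *imputation-to-majority* (rank–count knee; below-knee sequences are
   corrected to the nearest above-knee sequence within a Levenshtein
   cap, else dropped), *allowlist mapping* (non-members map to the unique
   nearest allowlist entry within the cap, else dropped), and an external
   *plugin* (any command obeying a two-column TSV in / two-column TSV out
   contract, for clustering correctors the package does not embed).
4. **Value encoding.** Corrected segment tuples become integer values
   organized in a *value tree* by the declared variable hierarchy:
   `parental` variables own independent scopes of `local` values, so the
   same UMI sequence under two different cells is two different objects;
   a *combinatorial* variable's value is its joint segment tuple.
5. **Value-space optimization.** Within every parent scope, values are
   renumbered `0..k-1` by descending read count. The species count of a
   variable then equals its maximum scope cardinality — the provable
   minimum for any renumbering that preserves the tree topology — which
   lets a short destination segment host a deep source segment (a 7-base
   UMI pool of 16384 sequences comfortably hosts the per-cell UMI
   repertoires of a library with millions of distinct UMI sequences
   overall). Because frequent values get small numbers, a capacity
   overflow drops the rarest values first.
6. **Translation.** Each destination segment renders its source variable by
   one of: `reassign` (mixed-radix encoding of the optimized value over the
   destination unit pool), `bequeath_pad` (source sequence padded with a
   constant base to the destination length), `conversion_table` (explicit
   sequence-to-sequence table, e.g. spatial barcodes), `passthrough`
   (verbatim sequence and per-base quality, for cDNA payloads) or
   `constant` (literal filler). Source segment qualities are bequeathed as
   the round-half-up mean of the contributing segments' average scores,
   clamped to [2, 40]; bases not associated with inherited values (pads,
   fillers) are written at exactly Phred 40.

## Numerical choices

* **Knee definition.** The knee of the descending rank–count curve is the
  maximum-curvature vertex of the (log10 rank, log10 count) polyline,
  measured as the turn angle between adjacent chord directions. For every
  run of equal counts the first and the last rank are kept as vertices;
  interior ranks of a run are collinear and carry no curvature, so this is
  exactly brute-force curvature over all interior points. Ties go to the
  smaller rank, which places the knee on the abundant side of a sharp
  cliff. Degenerate curves (two or fewer sequences, or all counts equal)
  accept everything — with no error tail there is nothing to cut.
* **Distance.** Levenshtein distance is the unit-cost edit distance over
  `{A,C,G,T,N}` (computed through `utils::adist`); `N` marks an uncalled
  base and matches nothing, including another `N`, so an aligned `N`–`N`
  pair costs one edit.
* **Tie-breaks.** Nearest-neighbor ties in imputation resolve to the
  higher count, then lexicographically; an ambiguous nearest allowlist
  entry is a drop, because correcting to an arbitrary barcode fabricates
  an identity. Frequency ties in value renumbering resolve
  lexicographically on the sequence tuple. Equidistant spots in spatial
  assignment resolve to the lowest spot index. All tie-breaks exist for
  one reason: identical inputs must give byte-identical outputs,
  regardless of chunking or platform.
* **Encoding.** `reassign` uses most-significant-unit-first mixed-radix
  encoding over the unit capacities; IUPAC positions digit over the code's
  base set in alphabetical order, allowlist units index in file order. Any
  injective scheme would do; this one is deterministic and sends small
  (frequent) values to the earliest pool entries.
* **Quality rounding.** Bequeathed averages round half-up; the destination
  per-base floor is Phred 2 (`#`), the ceiling Phred 40 (`I`).

## Design decisions

* **Valued vs. pass-through variables.** Whether a variable participates
  in value encoding is an explicit `valued` flag rather than being implied
  by its correction method. UMIs are the motivating case: they are valued
  (they must be reassigned into the destination UMI segment) but must not
  be knee-corrected — a UMI rank–count curve is nearly flat and a knee cut
  would destroy real molecules. The default (`valued = correction != "none"`)
  keeps payload declarations terse.
* **One-sided anchors.** When a segment's length is fixed, a single
  upstream *or* downstream motif suffices to place it. This lets pooled
  structures that differ only in an internal constant handle (the
  row-column-plate PCR case) be discriminated without a second mechanism.
* **Chunk contract.** Chunks are embarrassingly parallel between two
  single-node merge barriers (tally merge before correction tables; tree
  merge before optimization). Logical chunk size is decoupled from file
  I/O block size, so extreme chunk sizes change nothing but scheduling.
  Every artifact — correction tables, optimization maps, destination read
  multisets — is invariant to the chunking, and the test suite asserts
  this for chunk sizes 1, 7 and 1000.
* **Round trips.** `destinationAsSource()` mechanically derives the
  configuration under which emitted destination reads can themselves be
  interpreted, mirroring the parental–local hierarchy onto the
  destination variables. This is what makes translate-and-return
  ("round-trip") experiments one-liners.

## The simulator

`simulateStructuredReads()` generates FASTQ with per-read ground truth for
five read families: droplet scRNA-seq (16-base cell identifier + 12-base
UMI + 20-base gene-tag payload standing in for cDNA), row-column-plate
PCR (four structures pooled, full 384-well geometry: 16 row and 24 column
barcodes, Tag and Lox libraries with 50%/70% clonal-well calling),
combinatorial-index ATAC (four 8-base tiers over two index reads),
spatial bead arrays (barcoded beads with coordinates, for the
tiling/nearest-spot conversion-table builder) and anchored long reads
(barcode and variant regions between 20-base flanks at variable offsets).
UMIs per (cell, gene) are drawn from a geometric distribution truncated
to `1..maxUmis`, so local scopes have unequal sizes and optimization
minimality is exercised non-trivially. Errors are independent per-base
substitutions; barcode sets are drawn with pairwise Levenshtein distance
of at least 3, so a single substitution is unambiguously correctable.

What the simulator does *not* emulate: platform-specific error profiles
(indels, homopolymer slips, quality decay along the read), ambient
molecules and barcode swapping, transcriptome structure (gene tags are
fixed sequences, there is no alignment), or read-length heterogeneity
beyond the declared designs. Passing tests therefore demonstrate the
correctness of the interpretation/translation machinery under its own
model, not performance on any particular instrument's artifacts.

## Problem sizes

The test suite and the acceptance script run at desk scale, chosen so the
full suite completes in about two minutes on one CPU: the round-trip
experiment uses 200 cells × 100 gene tags with up to 8 UMIs per pair
(~43,000 reads) through a hypothetical structure with a two-unit 8-base
cell identifier (capacity 2560) and a 7-base UMI (capacity 16384);
optimization minimality is verified against exhaustive search on 500
random trees; the correction oracle compares all pairs on pools of up to
200 sequences; chunk invariance runs a ~4,700-read library at chunk sizes
1, 7 and 1000. The machinery itself is streaming and vectorized per
chunk, so nothing in the design limits it to these sizes.

## Known limitations

* Reads are taken as stored in FASTQ; no reverse-complement inference
  (declare a separate structure for the opposite orientation).
* Above-knee sequences always map to themselves; the package does not
  re-cluster the accepted set (an external plugin can).
* `conversion_table` destinations require a constant destination length
  per segment.
* The rank-difference statistic summarizes preservation of pairwise
  distances; it is a diagnostic, not a test with calibrated power.
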
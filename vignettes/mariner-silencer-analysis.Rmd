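---
title: "Silencer integrity and chromatin status of mariner transposon loci"
author: "marsil"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Silencer integrity and chromatin status of mariner transposon loci}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(marsil)
```

## The biological question

Mariner-like elements (MLEs) are cut-and-paste DNA transposons whose
transposase ORF carries, in its 3' third, a transcriptional silencer.  The
minimal silencer segment — called Delta8, a ~310 bp sub-interval of the
larger Delta7 segment — behaves like a Polycomb Response Element: it is
bound by YY1 together with NFAT-5 and other conserved transcription
factors, and represses nearby promoters largely through the PRC2 pathway.
At genome scale the question becomes statistical: across the hundreds of
degenerate MLE copies in a mammalian genome, do copies that still carry an
intact Delta8 segment (Sil+) sit in Polycomb-marked chromatin more often
than copies that lost it (Sil-)?

`marsil` implements that genome-scale analysis as a reusable pipeline, and
pairs it with a seeded synthetic-data generator so that every stage can be
exercised against known ground truth.

## The procedure

1. **Locus assembly.** RepeatMasker reports each element copy as 1–6
   high-scoring segment pairs (HSPs).  `assembleLoci()` groups HSPs into
   loci: the annotation's own fragment ID is authoritative when present;
   ID-less HSPs are grouped greedily when they share chromosome, family and
   strand, lie within `maxGap` (default 5000 bp), and have non-overlapping
   consensus spans ordered consistently with the strand.  Greedy groups are
   capped at 6 HSPs, the largest fragment count observed for these
   families.  Overlapping consensus spans are treated as independent
   copies, never merged.

2. **Silencer classification.** Each locus is classified against a
   per-family `SilencerDefinition`: **Sil+** when a single alignment block
   contains the whole Delta8 interval (complete and contiguous — no
   internal breakpoint), **U** when the blocks overlap Delta8 but no single
   block contains it (terminal truncation into the segment, or an internal
   indel), **Sil-** when nothing overlaps Delta8.  Containment is strict:
   no partial-coverage tolerance, because the U category exists precisely
   to capture indel-damaged segments and any tolerance would blur the
   Sil+/U boundary.  A `nearlyFullLength` flag (≤ 40 bp lost at either
   consensus end) is reported but plays no role in classification — the two
   notions are independent.

3. **Genic context.** A gene's "genic region" runs from its TSS to 5 kb
   past its 3' end (the span over which the silencer was experimentally
   effective): `[start, end + 5000)` for plus-strand genes,
   `[start − 5000, end)` for minus-strand genes, clipped at zero.  A locus
   is genic when its span overlaps any such region by ≥ 1 bp.  The overlap
   is evaluated on the full locus span by default so that Sil- loci (which
   have no Delta8 moiety) remain classifiable; a Delta8-moiety mode is
   available via `useSilencerSpan = TRUE`.

4. **Chromatin status.** For each locus and cell line, the marks whose
   ChIP-seq peaks overlap the target interval by ≥ 1 bp are collected, and
   a status is called from a closed rule set over five marks: Polycomb (P)
   from EZH2 and/or H3K27me3, Trithorax (T) from H3K27ac and/or H3K4me3,
   Su(var)39/HP1 heterochromatin (H) from H3K9me3; composites are spelled
   `T-H`, `P/H`, `P/T`, `P/T/H`, and `ucs` (undetermined chromatin status)
   means no peak at all.  Unknown marks are rejected rather than dropped,
   since the rule table is closed.  The target interval is the Delta8
   moiety where one exists and the locus span otherwise
   (`targetMode = "silencer_span"`); because published work is explicit
   about the moiety only for a handful of cloned elements, the pure
   locus-span mode is provided as well rather than guessed at.

5. **Statistics.** Per cell line, the frequency of a status component among
   loci with a *determined* status is computed — `ucs` calls never enter
   numerator or denominator, since an undetermined call carries no
   information about the underlying state.  Composites containing P count
   as Polycomb (a strict-P toggle exists).  Sil+ and Sil-/U frequencies are
   then compared across cell lines (the pairing unit) with a two-sided
   Wilcoxon signed-rank test and a paired Student t-test.  Whether the
   original t-test was paired is not documented; the paired form matches
   the signed-rank design and is the default, with a Welch variant
   available.  No multiple-testing correction is applied by default (raw
   p-values are reported); `stats::p.adjust` can be applied downstream.

6. **Heat map.** Loci in genic regions with a determined status in at least
   7 of the cell lines are selected, encoded as loci × (cell line ×
   {P, T, H}) with +1 (present), −1 (determined but absent), 0 (ucs), and
   clustered agglomeratively on rows and columns.

7. **Motif scanning.** NFAT-5 sites are exact literal occurrences of
   AAGGG/CCCTT (a both-strand search for AAGGG is equivalent).  YY1 sites
   use an ungapped position-weight profile scored as summed log2 odds in
   bits — the restriction of a profile HMM to a short gapless motif.  No
   state architecture or trained alignment for the original HMM is
   published, so the gapless profile is the minimal faithful model; the
   score threshold is an explicit parameter whose default is the minimum
   training-site score, so every training site is recovered by
   construction.  Overlapping hits are all reported.  Hit counts are
   projected onto consensus coordinates through the locus's alignment
   blocks, anchored at each hit's 5'-most base on the consensus
   orientation.

## The Wilcoxon signed-rank implementation

The test is implemented in the package rather than delegated, because the
analysis needs exact p-values in the presence of ties and zeros, which the
standard exact routine declines.  Zero differences are dropped (classic
treatment), tied absolute differences receive mid-ranks, and:

* **exact branch** (n ≤ `exactCutoff`, default 12): the null distribution
  of the positive-rank sum over all 2^n sign assignments is built by
  dynamic programming over doubled ranks (doubling makes tied mid-ranks
  integral); the two-sided p-value sums both symmetric tails.
* **normal branch** (n above the cutoff): tie-corrected variance
  `sum(ranks^2)/4` with a 0.5 continuity correction toward the mean.

The cutoff is an argument because per-binding-site association tests over
14 cell lines are small enough that a caller may prefer the exact branch
throughout.  Tests verify the exact branch against an independently written
full-enumeration oracle for every n ≤ 10, against
`stats::wilcox.test(exact = TRUE)` on tie-free data, and the normal branch
against the reference tie-corrected approximation.

## Coordinates and numerical choices

* All internal coordinates are 0-based half-open; RepeatMasker's 1-based
  inclusive genomic coordinates and its minus-strand `(left) end begin`
  consensus column order are normalized at read time, so no other module
  ever sees a format quirk.  The UCSC `rmsk` dialect's split class/family
  columns are rejoined so both dialects parse to identical records.
* Genomic↔consensus projection interpolates linearly within one alignment
  block (strand-aware: on minus-strand loci increasing consensus maps to
  decreasing genomic coordinate) and rounds to the nearest base.  Blocks
  generated by the simulator are always colinear, so round-trips are exact
  there; on real annotations with length-discrepant blocks the mapping is
  approximate within the block.
* Profile windows containing N score −∞ and can never reach a finite
  threshold; a sequence shorter than the model yields an empty hit list,
  not an error.
* Clustering uses Euclidean distance and complete linkage (both
  configurable; the original report specifies neither) with
  `stats::hclust`'s deterministic input-order tie-breaking.
* Degenerate statistical inputs produce flagged degenerate results
  (all-zero differences → p = 1; zero-variance differences → flagged NA)
  rather than errors, so batch runs over many subsets do not abort.

## The synthetic-data generator

`simulateDataset()` emits a complete input bundle — genome FASTA, BED6
genes, the repeat annotation in both dialects, per-cell-line peak BEDs, and
a JSON truth manifest — from a single seeded stream, in a fixed draw order
(consensus, genes, elements, peaks), so a seed reproduces the bundle
byte for byte.

Defaults mirror the published study scale and are fixed once:

| parameter | default | rationale |
|---|---|---|
| cell lines | 14 | the number inventoried genome-wide |
| elements | 187, split ≈ 95 Sil+ / 67 Sil- / 25 U | the heat-map selection counts |
| Polycomb event probability | 0.9 (Sil+) vs 0.7 (Sil-/U) | the reported ~91.5% vs ~73% densities |
| Trithorax / HP1 event probabilities | 0.3 / 0.2 | secondary statuses, minority of determined calls |
| `pUcs` | 0.35 | reproduces the reported 25–71% determined-status range (an extra ucs mass arises when no mark event fires) |
| divergence | 0.08 subs/bp | remnants tens of millions of years old |
| peak widths | 200–1000 bp | typical ENCODE narrow/broad peak scale |
| genome | 3 × 1 Mb, 60 genes of 10–25 kb | ~40% genic fraction at desk scale |

Element categories are drawn per copy: full-length (Sil+ by construction),
internal deletion strictly inside Delta8 (U, emitted as two HSPs sharing a
fragment ID), uniform terminal truncation (class follows from what
remains), and Delta8-absent truncation (Sil-).  Substitutions are i.i.d.
per base.  Peaks are centred on the Delta8 moiety (element centre for
Sil-), and elements are spaced by at least the maximum peak width so one
locus's peaks can never bleed onto a neighbour — this keeps the emitted
truth manifest exactly recoverable, which is what the recovery tests
assert.

Planted motifs: four YY1 profile sites at Delta7-relative positions 11,
382, 431, 475 and three NFAT-5 sites at 202, 293, 352, with chance
occurrences inside Delta7 scrubbed so consensus counts are exact by
construction.  The published positions are quoted inconsistently at one
point (202, 293 and 294 in one sentence; 202 and 352 in the next); 293 and
294 cannot both be exact AAGGG/CCCTT occurrences — overlapping occurrences
at offset 1 are mutually inconsistent — so the generator plants 202, 293
and 352, keeping three sites and both separately attested positions.

What the generator does **not** emulate: realistic nucleotide composition
or CpG decay, phylogenetically structured divergence, ChIP-seq read signal
(peaks are generated directly), nested or chimeric insertions, and
correlated statuses across cell lines.  Passing recovery tests therefore
demonstrate the pipeline's internal consistency — that classification,
projection and status calling invert the generative process — not
robustness to the full messiness of real annotations.

## Calibration and power

The matrix-level simulator (`simulateStatusMatrix()`) draws the status
matrix directly from the event model, which makes thousand-replicate
studies cheap.  Two standing checks:

* **Null calibration** — with equal Polycomb probabilities (0.8) in both
  groups, the signed-rank rejection rate at α = 0.05 over 1000 replicates
  must fall inside the binomial 99% band [0.033, 0.069].
* **Effect regime** — at the study scale (14 cell lines, 95/67/25 loci)
  with probabilities 0.9 vs 0.7, the rejection rate over 200 replicates
  must reach at least 0.8.

The test suite runs these at exactly those sizes; the other suites use
bundles of 20–90 elements over 0.2–0.5 Mb chromosomes, sizes chosen so the
whole suite exercises every path in a few minutes while the statistical
checks retain their nominal replicate counts.

## Packaged silencer definitions

`silencerDefinitions()` ships per-family Delta7/Delta8 consensus intervals
as data, not code.  Mos1 values are exact (Delta7 = 681–1212,
Delta8 = 903–1212 of the 1289 bp consensus; prose elsewhere calls Delta8
"the last 317 bp" while 903–1212 spans 310 bp — the interval is retained
and the discrepancy noted in the table).  For Hsmar1, Hsmar2, Himar1 and
Mcmar1 only segment lengths are published, so the shipped rows carry
Mos1-aligned approximations flagged in a `note` column and are intended to
be replaced by user-supplied coordinates from an actual consensus
alignment.

## Known limitations

* The greedy ID-less grouping is a backstop heuristic; RepeatMasker's own
  fragment IDs should be trusted whenever the dialect carries them.
* Consensus projection assumes no indels *within* a block; annotations
  violating that are mapped approximately.
* The YY1 profile is only as good as its training sites; the packaged
  default site set is synthetic (built around the YY1 CCAT core) and meant
  for simulation work, not for calling sites in real genomes.
* Full-genome inputs (hg19-scale RepeatMasker tables, ENCODE peak sets)
  are supported by the same readers but are not part of the test suite,
  which is desk-scale by design.
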
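---
title: "Methods: cistrome–transcriptome integration for direct target nomination"
author: "cistargets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cistrome-transcriptome integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cistargets)
```

## The problem

A transcription factor ChIP-seq experiment yields thousands of binding
peaks; a knockdown transcriptome yields hundreds of differentially
expressed genes.  Neither list alone identifies *direct* targets:
binding without regulation is pervasive, and regulation without nearby
binding is usually indirect.  `cistargets` implements the integration
chain that intersects the two bodies of evidence, with every rule made
explicit and every boundary testable.

## Coordinate model

All intervals are 0-based half-open (the BED convention) everywhere
inside the package; GTF input (1-based inclusive) is converted at the
reader boundary.  A single internal convention eliminates the class of
off-by-one errors that plague mixed-convention pipelines.  The overlap
of `[a, b)` and `[c, d)` is `max(0, min(b, d) − max(a, c))`; "1 bp
minimum overlap" therefore means abutting intervals do *not* intersect.

Each peak has an **anchor**: the summit (narrowPeak column 10) when
present, otherwise the interval midpoint.  The summit is the natural
point estimate of a point-source binding event, and all distance,
binning and mark-presence operations use it.

## Replicate intersection

`intersect_replicates()` keeps the replicate-1 peaks overlapping at
least one replicate-2 peak by `min_overlap` bp (default 1).  Retained
peaks keep replicate-1 coordinates: "reproducible" is a property of a
site, and re-deriving merged coordinates would silently change every
downstream anchor.  `merge-union` and `merge-intersection` modes exist
for users who prefer merged spans; each replicate-1 peak is counted
once however many replicate-2 peaks it touches.

## Genomic annotation

`annotate_peaks()` classifies anchors with precedence
**promoter > exon > intron > downstream > intergenic**, evaluated over
all genes.  The promoter window is the 10 kb upstream of a TSS
(strand-aware, boundary inclusive: 10,000 bp upstream is a promoter,
10,001 is not); the downstream window is the 10 kb past the TTS.
Promoter-first precedence reflects the usual reporting convention: a
peak in one gene's intron that also sits in another gene's promoter
window is biologically more informative as a promoter peak.  The
precedence is a function argument, not a constant.

When a GTF supplies several transcripts per gene the longest is kept,
so a gene enters downstream set logic exactly once.  Nearest-TSS
assignment is genome-wide on the peak's chromosome with no distance
cap; signed distances are negative upstream *in the gene's own
orientation*, ties break deterministically to the lexicographically
smaller `gene_id` and are flagged.  "Within 50 kb" uses a closed
boundary (≤).

## Regulatory-element classification

Mark presence is interval-overlap based: a mark is present when any of
its peak calls overlaps `[anchor − flank, anchor + flank)` by ≥ 1 bp,
with `flank = 1000` bp by default.  An overlap rule (rather than a
numeric signal threshold) matches how mark evidence is usually
distributed — as peak calls — and makes the classification a pure
function of three booleans:

| H3K27ac | H3K4me1 | H3K4me3 | state |
|---------|---------|---------|-------|
| ✓ | · | ✓ | cAP |
| ✓ | ✓ | ✗ | cAE |
| ✗ | · | ✓ | cIP |
| ✗ | ✓ | ✗ | cIE |
| ✓ | ✗ | ✗ | other |
| ✗ | ✗ | ✗ | other |

When all three marks co-occur the promoter mark dominates (cAP), the
standard chromatin-state convention.  One consequence worth noting:
swapping the me1 and me3 tracks exchanges cAE↔cAP and cIE↔cIP on the
six unambiguous mark combinations, but the two me1∧me3 cells are fixed
points of the dominance rule — the symmetry is tested exactly on that
domain.

Signal heatmaps use `bin_signal()`: 60 bins of 100 bp around each
anchor (6 kb total, a span that comfortably contains the bimodal
flanking-nucleosome signal of typical regulatory elements), counting
mark elements by midpoint.  Midpoint assignment is the simplest
deterministic fragment-center proxy; no read extension or shifting is
applied.  Open chromatin is flagged by ≥ 1 bp overlap between the
*full* peak interval and any ATAC interval — openness is a property of
the element, not of a window around its summit.

## Motif scanning with exact p-values

`build_pwm()` turns count matrices into log-odds scores
`log2(p/b)` in bits, with a per-column pseudocount mass (default 0.1,
distributed by the background) guaranteeing finite scores.  Scanning
scores every window on both strands (the minus-strand score is the
score of the window's reverse complement) and reports all hits at
`p ≤ threshold` (default 1e-4, the FIMO default); overlapping hits are
all kept, since "one or several copies" per peak is the quantity of
interest.  Windows containing `N` are skipped rather than scored with
background odds — deterministic and conservative.

The p-value is **exact**: the null distribution of the score of a
width-*w* background string is obtained by convolving the per-column
score distributions over the lattice of achievable sums.  Column
scores are snapped to a 1e-9-bit integer grid so the convolution is
drift-free, and scores within 1e-7 bits are treated as equal — five
orders of magnitude below any meaningful score difference.  If a
matrix's lattice would exceed 2^20 support points the function refuses
with an advisory instead of silently coarsening.  Unless supplied, the
0-order background is estimated from the scanned sequences themselves.

The shipped TRE/CRE matrices are *synthetic* (flagged in their file
names): sharp columns around the consensus anchors `TGA(G/C)TCA` and
`TGACGTCA`, with a mild 55:45 G/C preference at the TRE's degenerate
position so that the single best-scoring word is unique and
significant at the default threshold.  Real scans should supply
database matrices; the PFM file given at runtime is always
authoritative.

## Differential expression and concordance

DE tables (gene, contrast, log2FC, p) are inputs; model fitting is out
of scope.  Within each contrast p-values are adjusted by
Benjamini–Hochberg (the default of the moderated-statistics tools that
produce such tables), *per contrast* rather than pooled, because the
two knockdown contrasts are separate comparisons.  The filter is
|fold| ≥ 1.25 (inclusive) with FDR < 0.05 (strict).  No upper fold cap
is applied by default — an observed-range reading of "1.25- to
10-fold"; capping would discard the strongest responders (an optional
`max_fold` exists).  The high-confidence set is the per-direction
intersection across the two contrasts; direction-discordant genes are
excluded from both sides and reported.

## Preranked enrichment

`enrichment_score()` walks the log2FC-ranked list, adding
`|metric|^p / N_R` at set members and subtracting `1/(N − N_hits)`
elsewhere; the ES is the extremum of the running sum.  The weighting
exponent defaults to 1 (the preranked tool's default) and is exposed.
Ranking ties break by gene id for determinism.  The null model is
gene-set permutation — random same-size sets drawn from the list —
which is the only null available when all that exists is a ranked
list.  NES and p are sign-stratified
(`p = (1 + #{same-sign null ≥ |ES|}) / (1 + #same-sign null)`), and a
simple sign-stratified empirical FDR over the tested collection is
reported.  When no same-sign null score exists the p-value is reported
as 1 and flagged rather than divided by zero.

## The synthetic-data generator

`simulate_study()` is first-class, tested code, and its defaults *are*
the study conditions used throughout the test suite: seed 1234, two
500-kb chromosomes, 60 non-overlapping stranded genes with 2–8 exons,
400 reproducible peaks in proportions other 0.60 / cAE 0.27 /
cIE 0.09 / cAP 0.03 / cIP 0.01 (active enhancers dominating the
classified fraction, as in real transcription-factor cistromes), mark
intervals planted as bimodal flanks ±600 bp from each anchor,
open-chromatin probabilities 0.964 (cAE) and 0.928 (cAP) versus low
rates elsewhere, TRE planted in 90% and CRE in 20% of peaks, and 20
direct-target genes given 2-fold knockdown effects, concordant across
two simulated siRNA contrasts.

Identifiability at zero noise is geometric, not statistical: peaks sit
on a ≥ 1.8-kb-spaced lattice, so one peak's planted marks
(±600 ± 150 bp) can never enter a neighbour's ±1-kb presence window;
each direct-target gene is chosen with its TSS ≥ 4 kb from any other
TSS and receives a classified peak within 1 kb of it, so the
nearest-TSS assignment is unambiguous; replicate-2 jitter is capped at
±50 bp so every 300-bp shared peak still overlaps its twin, while
replicate-specific decoys (5% by default) occupy disjoint lattice
slots and vanish at intersection.  Motifs are embedded by base
replacement, keeping all coordinates stable.  DE p-values come from a
one-sample z-model whose standard error equals the null log2FC spread,
making null p-values exactly Uniform(0, 1) while planted 2-fold
effects are significant at any practical threshold.  A single global
seed feeds independent sub-streams (genome, genes, peaks/marks,
motifs, DE), so changing one component's parameters does not shift
another's draws.

What the generator does *not* emulate — and what passing tests
therefore do not show about real data: read-level noise and peak-call
uncertainty, mappability and copy-number artifacts, correlated mark
signal strength (presence is binary), enhancer–gene looping beyond
nearest-TSS, probe-level microarray structure, and realistic gene
density (the miniature genome is ~50× denser in genes than human, so
feature-category and TSS-distance distributions are compressed
relative to a real genome).

## Problem sizes and determinism

The test suite and `scripts/acceptance.R` run the full default
simulation (400 peaks, 60 genes, 1 Mb genome), 100+ random
brute-force-oracle fixtures of up to 10³ elements, exhaustive 4^w
motif enumerations for widths ≤ 6, 100 null DE tables, 200 noise GSEA
repeats at 500 permutations and 20 planted-set runs at 1000
permutations — sizes chosen so any single check completes in seconds
while keeping binomial error bars (3 SE) tight enough to be
meaningful.  Every artifact of a run is a pure function of the seed;
fixed-seed runs are byte-identical, which the suite asserts on the
generator's complete file output.

## Known limitations

* Nearest-TSS is a heuristic target-assignment model; distal enhancers
  regulating a non-nearest gene are mis-assigned by construction.
* Mark presence ignores signal magnitude; a weak flanking mark call
  counts as fully as a strong one (an optional minimum-count mode over
  the central window is a natural extension).
* The empirical GSEA FDR is the simple sign-stratified pooled version,
  not the full rank-of-NES procedure.
* Probe-to-gene collapsing of probe-level DE tables must happen
  upstream (tables are assumed gene-level).
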
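# cistargets

Integration of a transcription factor's cistrome (its genome-wide
ChIP-seq binding sites) with chromatin evidence and knockdown
transcriptomics to nominate **candidate direct target genes**.

Mapping where a transcription factor binds says nothing about which
genes it regulates; profiling what changes after knocking it down says
nothing about which changes are direct.  `cistargets` implements the
standard integration recipe that joins the two:

1. **Reproducible binding sites.**  Peaks called in two biological
   replicates are intersected (≥ 1 bp half-open overlap,
   `max(0, min(b, d) − max(a, c))`), keeping only sites seen in both.
2. **Genomic annotation.**  Each peak anchor (summit, or interval
   midpoint) is classified as promoter (≤ 10 kb upstream of a TSS,
   strand-aware), exon, intron, downstream (≤ 10 kb past a TTS) or
   intergenic, and assigned to the gene with the nearest TSS, with the
   signed distance *d* = (anchor − TSS) · (±1 by strand).
3. **Regulatory-element classes.**  Presence of H3K27ac, H3K4me1 and
   H3K4me3 peak calls within ±1 kb of each anchor feeds a rule table:
   ac ∧ me3 → candidate active promoter (cAP); ac ∧ me1 ∧ ¬me3 →
   candidate active enhancer (cAE); ¬ac ∧ me3 → cIP; ¬ac ∧ me1 ∧ ¬me3 →
   cIE; otherwise *other*.  ATAC-seq overlap flags open chromatin.
4. **Motif content.**  Peak sequences are scanned on both strands with
   position weight matrices (TRE `TGA(G/C)TCA`, CRE `TGACGTCA`) using
   log-odds scores *s(x) = Σⱼ log₂(pⱼ(xⱼ)/b(xⱼ))* and **exact**
   p-values P(S ≥ s) computed by convolving the per-column score
   distributions over the background — the FIMO-style null, computed
   without approximation.
5. **High-confidence regulated genes.**  Per knockdown contrast, genes
   with |fold change| ≥ 1.25 (inclusive) and BH-adjusted FDR < 0.05
   (strict) are selected; genes passing in the *same direction under
   both independent siRNAs* form the high-confidence set.
6. **Direct-target nomination.**  High-confidence genes whose nearest
   TSS receives ≥ 1 peak in a regulatory class (cAP/cAE/cIP/cIE) are
   nominated as candidate direct targets; the remainder are candidate
   indirect targets.

A preranked GSEA (weighted running-sum enrichment score with gene-set
permutation normalization) and the 2^−ΔΔCt RT-qPCR quantification are
included, as is a fully seeded **synthetic-data generator** that plants
ground truth — peak classes, motif occurrences, open chromatin, and
direct-target effects — so the whole pipeline can be validated
end-to-end.

## Worked example

```r
library(cistargets)

sim <- simulate_study(sim_config(seed = 1234))   # planted ground truth
res <- run_pipeline(sim$rep1, sim$rep2, sim$genes, sim$marks,
                    sim$atac, sim$de, genome = sim$genome)

res$state_summary
#>   state count fraction open_fraction
#> 1   cAP    12     0.03    0.91666667
#> 2   cAE   108     0.27    0.98148148
#> 3   cIP     4     0.01    0.50000000
#> 4   cIE    36     0.09    0.22222222
#> 5 other   240     0.60    0.03333333

res$motifs$summary
#>   motif n_peaks_with_hit fraction
#> 1   TRE              362   0.9050
#> 2   CRE               83   0.2075

res$venn
#> regulated_only     bound_only           both
#>              0             38             20

head(res$targets$nominations, 4)
#>    gene_id direction n_peaks
#> 1 gene_010        up       4
#> 2 gene_014      down       5
#> 3 gene_018      down       6
#> 4 gene_019      down       3
```

Reading the output: of the 400 reproducible peaks, 40% fall in the four
candidate regulatory classes, dominated by active enhancers (cAE),
which are almost all in open chromatin; 90.5% of peaks carry at least
one TRE motif versus 20.8% for CRE, the classic AP-1 contrast.  All 20
genes planted as direct targets — and no others — are nominated, each
supported by its classified peaks, with the planted knockdown
direction recovered.

A thin command-line wrapper over the same functions is shipped at
`inst/scripts/cistrome.R` (subcommands `intersect`, `annotate`,
`classify`, `scan`, `de-filter`, `gsea`, `integrate`, `simulate`).

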
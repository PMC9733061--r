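#' Bundled synthetic TRE/CRE frequency matrices
#'
#' Returns the two position frequency matrices shipped with the package:
#' a TRE (TPA-responsive element, consensus `TGA(G/C)TCA` with a mild G
#' preference at the degenerate position) and a CRE (cAMP-responsive
#' element, consensus `TGACGTCA`) matrix.  The counts are synthetic --
#' invented for simulation and testing, not taken from any motif
#' database -- which is also flagged in the file names.
#'
#' @return Named list of 4 x width count matrices (`TRE`, `CRE`).
#' @export
cistargets_pfms <- function() {
  c(read_pfm(system.file("extdata", "tre_synthetic.pfm",
                         package = "cistargets")),
    read_pfm(system.file("extdata", "cre_synthetic.pfm",
                         package = "cistargets")))
}

#' End-to-end cistrome-transcriptome integration
#'
#' Chains the whole analysis on in-memory objects: replicate peak
#' intersection, genomic annotation with nearest-TSS assignment,
#' regulatory-state classification with ATAC openness, optional motif
#' scanning, the fold-change/FDR filter with two-contrast concordance,
#' and direct-target nomination with the Venn summary.
#'
#' @param rep1,rep2 replicate [peak_set()]s.
#' @param genes a [gene_models()] table.
#' @param marks named list with `H3K27ac`, `H3K4me1`, `H3K4me3`
#'   [peak_set()]s.
#' @param atac optional ATAC [peak_set()].
#' @param de optional DE table (`gene_id`, `contrast`, `log2fc`,
#'   `pvalue`) with exactly two contrasts.
#' @param genome optional `DNAStringSet` or FASTA path for motif
#'   scanning.
#' @param pwms optional named list of count matrices or [build_pwm()]
#'   objects (defaults to [cistargets_pfms()] when a genome is given).
#' @param min_overlap replicate intersection overlap (default 1 bp).
#' @param promoter_window,downstream_window annotation windows (bp).
#' @param flank mark-presence half-window (bp).
#' @param threshold_p motif scan p-value threshold.
#' @param min_fold,max_fdr DE filter parameters.
#' @return A list: `common_peaks`, `annotations`, `feature_distribution`,
#'   `distance_distribution`, `classifications`, `state_summary`,
#'   `motifs` (or `NULL`), `de_sets`, `highconf`, `peak_genes`,
#'   `targets`, `venn`.
#' @export
run_pipeline <- function(rep1, rep2, genes, marks, atac = NULL, de = NULL,
                         genome = NULL, pwms = NULL,
                         min_overlap = 1L,
                         promoter_window = 10000L,
                         downstream_window = 10000L,
                         flank = 1000L, threshold_p = 1e-4,
                         min_fold = 1.25, max_fdr = 0.05) {
  common <- intersect_replicates(rep1, rep2, min_overlap)
  ann <- annotate_peaks(common, genes, promoter_window, downstream_window)
  cls <- classify_chromatin_states(common, marks$H3K27ac, marks$H3K4me1,
                                   marks$H3K4me3, atac, flank)
  motifs <- NULL
  if (!is.null(genome)) {
    if (is.null(pwms)) pwms <- cistargets_pfms()
    motifs <- peak_motif_fractions(common, genome, pwms, threshold_p)
  }
  de_sets <- highconf <- targets <- venn <- NULL
  pg <- classified_peak_genes(cls, ann)
  if (!is.null(de)) {
    de_sets <- filter_de(de, min_fold = min_fold, max_fdr = max_fdr)
    if (length(de_sets) != 2L) {
      stop("the DE table must contain exactly two contrasts")
    }
    highconf <- concordant_genes(de_sets[[1]], de_sets[[2]])
    targets <- nominate_direct_targets(highconf, pg)
    venn <- venn_summary(highconf, pg)
  }
  list(common_peaks = common,
       annotations = ann,
       feature_distribution = feature_distribution(ann),
       distance_distribution = distance_distribution(ann),
       classifications = cls,
       state_summary = state_summary(cls),
       motifs = motifs,
       de_sets = de_sets,
       highconf = highconf,
       peak_genes = pg,
       targets = targets,
       venn = venn)
}
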
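#' Genes receiving classified regulatory peaks
#'
#' Restricts a regulatory classification to the selected states (by
#' default the four candidate regulatory element classes) and groups the
#' retained peaks by their nearest-TSS gene.
#'
#' @param classifications output of [classify_chromatin_states()].
#' @param annotations output of [annotate_peaks()]; must cover every peak
#'   in `classifications`.
#' @param states states to keep (default `c("cAP","cAE","cIP","cIE")`).
#' @return A named list (sorted by `gene_id`), each element a
#'   `data.frame` of that gene's supporting peaks (`peak_name`, `state`,
#'   `open_chromatin`, `signed_tss_distance`).
#' @export
classified_peak_genes <- function(classifications, annotations,
                                  states = c("cAP", "cAE", "cIP", "cIE")) {
  missing <- setdiff(classifications$peak_name, annotations$peak_name)
  if (length(missing)) {
    stop("classification/annotation tables out of sync; e.g. peak '",
         missing[1], "' has no annotation")
  }
  keep <- classifications[classifications$state %in% states, , drop = FALSE]
  if (nrow(keep) == 0L) return(structure(list(), names = character(0)))
  ann <- annotations[match(keep$peak_name, annotations$peak_name), ]
  merged <- data.frame(peak_name = keep$peak_name, state = keep$state,
                       open_chromatin = keep$open_chromatin,
                       gene_id = ann$gene_id,
                       signed_tss_distance = ann$signed_tss_distance,
                       stringsAsFactors = FALSE)
  merged <- merged[!is.na(merged$gene_id), , drop = FALSE]
  out <- split(merged[, c("peak_name", "state", "open_chromatin",
                          "signed_tss_distance")],
               merged$gene_id)
  out[order(names(out))]
}

#' Nominate candidate direct target genes
#'
#' Intersects the high-confidence knockdown-regulated gene set with the
#' genes carrying at least one classified regulatory peak at their nearest
#' TSS.  Regulated genes without such a peak are returned as candidate
#' indirect targets; bound genes outside the regulated set are returned
#' for completeness.
#'
#' @param highconf output of [concordant_genes()].
#' @param peak_genes output of [classified_peak_genes()].
#' @return A list: `nominations` (data.frame `gene_id`, `direction`,
#'   `n_peaks`, sorted by gene), `supporting_peaks` (named list of peak
#'   tables for the nominated genes), `indirect` and
#'   `bound_not_regulated` character vectors.
#' @export
nominate_direct_targets <- function(highconf, peak_genes) {
  bound <- names(peak_genes)
  direct <- sort(intersect(highconf$high_confidence, bound))
  direction <- ifelse(direct %in% highconf$up, "up", "down")
  nominations <- data.frame(
    gene_id = direct,
    direction = direction,
    n_peaks = vapply(peak_genes[direct], nrow, integer(1),
                     USE.NAMES = FALSE) %||% integer(0),
    row.names = NULL, stringsAsFactors = FALSE)
  if (length(direct) == 0L) {
    nominations <- data.frame(gene_id = character(), direction = character(),
                              n_peaks = integer(), stringsAsFactors = FALSE)
  }
  list(nominations = nominations,
       supporting_peaks = peak_genes[direct],
       indirect = sort(setdiff(highconf$high_confidence, bound)),
       bound_not_regulated = sort(setdiff(bound,
                                          highconf$high_confidence)))
}

#' Venn summary of regulated and bound gene sets
#'
#' @param highconf output of [concordant_genes()] (or any list with a
#'   `high_confidence` vector).
#' @param peak_genes output of [classified_peak_genes()] or a character
#'   vector of bound genes.
#' @return Named integer vector `c(regulated_only, bound_only, both)`.
#' @export
venn_summary <- function(highconf, peak_genes) {
  reg <- unique(highconf$high_confidence)
  bound <- unique(if (is.character(peak_genes)) peak_genes else
    names(peak_genes))
  both <- length(intersect(reg, bound))
  c(regulated_only = length(reg) - both,
    bound_only = length(bound) - both,
    both = both)
}
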
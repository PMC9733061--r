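#' Read a differential-expression table
#'
#' Expects a tab-separated file with a header and at least the columns
#' `gene_id`, `contrast`, `log2fc`, `pvalue` (an `fdr` column is used when
#' present, otherwise computed per contrast with [adjust_fdr()]).
#'
#' @param path path to the TSV file.
#' @return A `data.frame` with one row per (gene, contrast).
#' @export
read_de_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  de <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("gene_id", "contrast", "log2fc", "pvalue")
  miss <- setdiff(need, names(de))
  if (length(miss)) {
    stop("DE table '", path, "' is missing column(s): ",
         paste(miss, collapse = ", "))
  }
  if (anyDuplicated(de[, c("gene_id", "contrast")])) {
    stop("DE table has duplicated (gene_id, contrast) records")
  }
  if (!"fdr" %in% names(de)) {
    de$fdr <- NA_real_
    for (ct in unique(de$contrast)) {
      i <- de$contrast == ct
      de$fdr[i] <- adjust_fdr(stats::setNames(de$pvalue[i], de$gene_id[i]))
    }
  }
  de
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (`q_i = min_{j >= i} p_(j) * m / j`, clipped at
#' 1), returned in the input order with input names preserved.  Input
#' p-values must lie in `(0, 1]`.
#'
#' @param pvalues numeric vector of raw p-values, optionally named by gene.
#' @return Adjusted values in the same order.
#' @export
adjust_fdr <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues <= 0) || any(pvalues > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  stats::setNames(stats::p.adjust(pvalues, method = "BH"), names(pvalues))
}

#' Fold-change / FDR differential-expression filter
#'
#' Per contrast, selects up-regulated genes with
#' `log2fc >= log2(min_fold)` and down-regulated genes with
#' `log2fc <= -log2(min_fold)` (fold boundary inclusive), both subject to
#' the strict significance rule `fdr < max_fdr`.  An optional upper fold
#' cap can be supplied but is off by default.
#'
#' @param records DE table with `gene_id`, `contrast`, `log2fc` and `fdr`
#'   (computed from `pvalue` with [adjust_fdr()] when absent).
#' @param min_fold minimum linear fold change, `> 1` (default 1.25).
#' @param max_fdr strict FDR threshold (default 0.05).
#' @param max_fold optional maximum linear fold change (inclusive);
#'   `NULL` for no cap.
#' @return Named list, one entry per contrast, each a list with `up` and
#'   `down` character vectors of gene ids.
#' @export
filter_de <- function(records, min_fold = 1.25, max_fdr = 0.05,
                      max_fold = NULL) {
  if (min_fold <= 1) stop("min_fold must be > 1")
  if (!"fdr" %in% names(records) || all(is.na(records$fdr))) {
    records$fdr <- NA_real_
    for (ct in unique(records$contrast)) {
      i <- records$contrast == ct
      records$fdr[i] <- adjust_fdr(records$pvalue[i])
    }
  }
  lfc <- log2(min_fold)
  cap <- if (is.null(max_fold)) Inf else log2(max_fold)
  out <- lapply(split(records, records$contrast), function(d) {
    sig <- d$fdr < max_fdr & abs(d$log2fc) <= cap
    list(up = sort(d$gene_id[sig & d$log2fc >= lfc]),
         down = sort(d$gene_id[sig & d$log2fc <= -lfc]))
  })
  out
}

#' Two-contrast concordant gene sets
#'
#' The high-confidence regulated set: genes called in the same direction
#' by both independent knockdown contrasts.  `up = upA` \eqn{\cap}
#' `upB`, `down = downA` \eqn{\cap} `downB`; genes passing in opposite
#' directions are excluded from both and listed in the discordance report.
#'
#' @param setsA,setsB lists with `up` and `down` gene-id vectors, as
#'   returned per contrast by [filter_de()].
#' @return A list with `up`, `down`, `high_confidence`
#'   (`up` \eqn{\cup} `down`) and `discordant`.
#' @export
concordant_genes <- function(setsA, setsB) {
  up <- intersect(setsA$up, setsB$up)
  down <- intersect(setsA$down, setsB$down)
  discordant <- sort(union(intersect(setsA$up, setsB$down),
                           intersect(setsA$down, setsB$up)))
  up <- sort(setdiff(up, discordant))
  down <- sort(setdiff(down, discordant))
  list(up = up, down = down,
       high_confidence = sort(c(up, down)),
       discordant = discordant)
}

#' Relative quantification by the delta-delta-Ct method
#'
#' Computes the linear fold change
#' `2^-((Ct_target,treated - Ct_ref,treated) -
#' (Ct_target,control - Ct_ref,control))` used for RT-qPCR data
#' normalized to a housekeeping reference gene.
#'
#' @param ct_target_treated,ct_reference_treated Ct values in the treated
#'   condition for the target and reference gene.
#' @param ct_target_control,ct_reference_control Ct values in the control
#'   condition.
#' @return Linear fold change (1 = no change, 0.5 = halved).
#' @examples
#' ddct_fold_change(25, 20, 24, 20)  # ddCt = 1 -> 0.5
#' @export
ddct_fold_change <- function(ct_target_treated, ct_reference_treated,
                             ct_target_control, ct_reference_control) {
  cts <- c(ct_target_treated, ct_reference_treated,
           ct_target_control, ct_reference_control)
  if (any(!is.finite(cts)) || any(cts <= 0)) {
    stop("Ct values must be finite and positive")
  }
  ddct <- (ct_target_treated - ct_reference_treated) -
    (ct_target_control - ct_reference_control)
  2^(-ddct)
}
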
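#' Nearest-TSS assignment
#'
#' Assigns each peak to the gene whose transcription start site is closest
#' to the peak anchor on the same chromosome, and reports the signed
#' distance in the gene's own orientation:
#' `distance = (anchor - tss) * (+1 for '+' genes, -1 for '-' genes)`, so a
#' negative distance always means "upstream of the gene".  Ties in absolute
#' distance are broken deterministically towards the lexicographically
#' smaller `gene_id` and flagged.
#'
#' @param peaks a [peak_set()].
#' @param genes a [gene_models()] table.
#' @return A `data.frame` with `peak_name`, `gene_id` (`NA` when no gene
#'   shares the chromosome), `signed_tss_distance` and logical `tie`.
#' @export
nearest_tss <- function(peaks, genes) {
  out <- data.frame(peak_name = peaks$name,
                    gene_id = NA_character_,
                    signed_tss_distance = NA_integer_,
                    tie = FALSE,
                    stringsAsFactors = FALSE)
  for (chr in unique(peaks$chrom)) {
    gi <- which(genes$chrom == chr)
    pi <- which(peaks$chrom == chr)
    if (length(gi) == 0L) next
    g <- genes[gi, , drop = FALSE]
    ord <- order(g$gene_id)
    g <- g[ord, , drop = FALSE]
    d <- outer(peaks$anchor[pi], g$tss, `-`)      # peaks x genes
    absd <- abs(d)
    j <- apply(absd, 1L, which.min)               # first = smaller gene_id
    mind <- absd[cbind(seq_along(pi), j)]
    ties <- rowSums(absd == mind) > 1L
    sign <- ifelse(g$strand[j] == "+", 1L, -1L)
    out$gene_id[pi] <- g$gene_id[j]
    out$signed_tss_distance[pi] <- d[cbind(seq_along(pi), j)] * sign
    out$tie[pi] <- ties
  }
  out
}

# category of each anchor with respect to a single gene; NA when none applies
.gene_context <- function(anchor, gene, promoter_window, downstream_window) {
  up <- if (gene$strand == "+") gene$tss - anchor else anchor - gene$tss
  if (up >= 1L && up <= promoter_window) return("promoter")
  if (anchor >= gene$tx_start && anchor < gene$tx_end) {
    ex <- gene$exons[[1]]
    inex <- any(anchor >= ex[, 1] & anchor < ex[, 2])
    return(if (inex) "exon" else "intron")
  }
  dn <- if (gene$strand == "+") anchor - gene$tts else gene$tts - anchor
  if (dn >= 1L && dn <= downstream_window) return("downstream")
  NA_character_
}

#' Annotate peaks against gene models
#'
#' Classifies each peak anchor into one of five genomic feature categories
#' -- `promoter` (within `promoter_window` bp upstream of any TSS,
#' strand-aware), `exon` / `intron` (anchor inside a gene body),
#' `downstream` (within `downstream_window` bp past any TTS) or
#' `intergenic` -- with precedence promoter > exon > intron > downstream >
#' intergenic when several gene contexts apply, and attaches the
#' nearest-TSS gene and signed distance from [nearest_tss()].
#'
#' @param peaks a [peak_set()].
#' @param genes a [gene_models()] table.
#' @param promoter_window,downstream_window window sizes in bp
#'   (default 10 kb each).
#' @return A `data.frame` with `peak_name`, `category`, `gene_id`,
#'   `signed_tss_distance` and `tie`.
#' @export
annotate_peaks <- function(peaks, genes, promoter_window = 10000L,
                           downstream_window = 10000L) {
  stopifnot(promoter_window > 0L, downstream_window > 0L)
  if (nrow(genes) == 0L) stop("gene model collection is empty")
  prec <- c("promoter", "exon", "intron", "downstream")
  category <- rep("intergenic", nrow(peaks))
  missing_chrom <- !(peaks$chrom %in% genes$chrom)
  if (any(missing_chrom)) {
    warning(sum(missing_chrom),
            " peak(s) on chromosomes absent from the gene model; ",
            "classified intergenic with no assigned gene")
  }
  for (i in which(!missing_chrom)) {
    gi <- which(genes$chrom == peaks$chrom[i])
    cats <- vapply(gi, function(j) {
      ctx <- .gene_context(peaks$anchor[i], genes[j, , drop = FALSE],
                           promoter_window, downstream_window)
      if (is.na(ctx)) NA_integer_ else match(ctx, prec)
    }, integer(1))
    cats <- cats[!is.na(cats)]
    if (length(cats)) category[i] <- prec[min(cats)]
  }
  nt <- nearest_tss(peaks, genes)
  data.frame(peak_name = peaks$name, category = category,
             gene_id = nt$gene_id,
             signed_tss_distance = nt$signed_tss_distance,
             tie = nt$tie, stringsAsFactors = FALSE)
}

#' Histogram of absolute nearest-TSS distances
#'
#' Bins `|signed_tss_distance|` at the supplied break points; the boundary
#' rule is closed ("within 50 kb" means `<= 50000`).  Peaks without an
#' assigned gene are excluded from the histogram and reported separately.
#'
#' @param annotations output of [annotate_peaks()] (or any data.frame with
#'   a `signed_tss_distance` column).
#' @param breaks strictly increasing distance thresholds in bp.
#' @return A `data.frame` with one row per bin (`bin`, `count`, `fraction`,
#'   `cum_fraction`), the last bin open-ended; attribute `n_unassigned`
#'   carries the excluded count.
#' @export
distance_distribution <- function(annotations,
                                  breaks = c(10000L, 50000L, 100000L)) {
  if (is.unsorted(breaks, strictly = TRUE)) {
    stop("breaks must be strictly increasing")
  }
  d <- annotations$signed_tss_distance
  n_unassigned <- sum(is.na(d))
  d <- abs(d[!is.na(d)])
  edges <- c(-1, breaks, Inf)
  labels <- c(sprintf("<=%d", breaks), sprintf(">%d", breaks[length(breaks)]))
  idx <- findInterval(d, edges, left.open = TRUE)  # bins are (lo, hi]
  counts <- tabulate(idx, nbins = length(labels))
  total <- sum(counts)
  out <- data.frame(bin = labels, count = counts,
                    fraction = if (total > 0) counts / total else
                      rep(0, length(counts)),
                    stringsAsFactors = FALSE)
  out$cum_fraction <- cumsum(out$fraction)
  attr(out, "n_unassigned") <- n_unassigned
  out
}

#' Fraction of peaks within a distance of the nearest TSS
#'
#' @param annotations output of [annotate_peaks()].
#' @param within distance threshold in bp (closed boundary; default 50 kb).
#' @return Fraction of assigned peaks with `|distance| <= within`.
#' @export
fraction_within_tss <- function(annotations, within = 50000L) {
  d <- annotations$signed_tss_distance
  d <- d[!is.na(d)]
  if (length(d) == 0L) return(NA_real_)
  mean(abs(d) <= within)
}

#' Genomic feature category distribution
#'
#' @param annotations output of [annotate_peaks()].
#' @return A `data.frame` with one row per category (`category`, `count`,
#'   `fraction`); fractions sum to 1.
#' @export
feature_distribution <- function(annotations) {
  if (nrow(annotations) == 0L) stop("empty annotation table")
  lev <- c("promoter", "exon", "intron", "downstream", "intergenic")
  counts <- table(factor(annotations$category, levels = lev))
  data.frame(category = lev, count = as.integer(counts),
             fraction = as.numeric(counts) / nrow(annotations),
             stringsAsFactors = FALSE)
}
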
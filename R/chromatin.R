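#' Binned mark signal around peak anchors
#'
#' Builds the peaks x bins count matrix used for heatmaps and QC: for each
#' peak, `n_bins` bins of `bin_size` bp are laid out around the anchor
#' (total window `n_bins * bin_size`, anchors at the left edge of bin
#' `n_bins/2 + 1`), and bin `j` counts the mark elements whose midpoint
#' falls in `[anchor - window/2 + (j-1)*bin_size,
#' anchor - window/2 + j*bin_size)`.  Mark elements are intervals (peak
#' calls or reads reduced to intervals); the midpoint is
#' `floor((start + end)/2)`.  Bins clipped at a chromosome start simply
#' collect no counts; such peaks are flagged in the `clipped` attribute.
#'
#' @param peaks a [peak_set()].
#' @param marks a [peak_set()] of mark intervals.
#' @param n_bins even number of bins (default 60).
#' @param bin_size bin width in bp (default 100).
#' @return An integer matrix (peak names x bins) with attributes
#'   `mark_name`, `bin_size`, `window` and `clipped`.
#' @export
bin_signal <- function(peaks, marks, n_bins = 60L, bin_size = 100L) {
  n_bins <- as.integer(n_bins)
  bin_size <- as.integer(bin_size)
  if (n_bins %% 2L != 0L) stop("n_bins must be even")
  if (bin_size <= 0L) stop("bin_size must be positive")
  window <- n_bins * bin_size
  half <- window %/% 2L
  mat <- matrix(0L, nrow = nrow(peaks), ncol = n_bins,
                dimnames = list(peaks$name, NULL))
  clipped <- peaks$name[peaks$anchor < half]
  if (nrow(marks) > 0L && nrow(peaks) > 0L) {
    mid <- (marks$start + marks$end) %/% 2L
    left <- peaks$anchor - half
    lv <- union(peaks$chrom, marks$chrom)
    win <- GenomicRanges::GRanges(
      factor(peaks$chrom, levels = lv),
      IRanges::IRanges(start = pmax(left, 0L) + 1L,
                       end = peaks$anchor + half))
    pts <- GenomicRanges::GRanges(factor(marks$chrom, levels = lv),
                                  IRanges::IRanges(start = mid + 1L,
                                                   width = 1L))
    hits <- GenomicRanges::findOverlaps(pts, win)
    if (length(hits) > 0L) {
      q <- S4Vectors::queryHits(hits)
      s <- S4Vectors::subjectHits(hits)
      bin <- (mid[q] - left[s]) %/% bin_size + 1L
      ok <- bin >= 1L & bin <= n_bins
      tab <- table(factor(s[ok], levels = seq_len(nrow(peaks))),
                   factor(bin[ok], levels = seq_len(n_bins)))
      mat <- mat + matrix(as.integer(tab), nrow = nrow(peaks),
                          dimnames = dimnames(mat))
    }
  }
  attr(mat, "mark_name") <- attr(marks, "source_label")
  attr(mat, "bin_size") <- bin_size
  attr(mat, "window") <- window
  attr(mat, "clipped") <- clipped
  mat
}

#' Histone-mark presence around peak anchors
#'
#' A mark is present at a peak when any mark interval overlaps the
#' half-open window `[anchor - flank, anchor + flank)` by at least 1 bp.
#'
#' @param peaks a [peak_set()].
#' @param marks a [peak_set()] of mark intervals.
#' @param flank half-window in bp around the anchor (default 1000).
#' @return Logical vector along `peaks`.
#' @export
mark_presence <- function(peaks, marks, flank = 1000L) {
  if (flank <= 0L) stop("flank must be positive")
  if (nrow(peaks) == 0L) return(logical(0))
  if (nrow(marks) == 0L) return(rep(FALSE, nrow(peaks)))
  win <- peak_set(peaks$chrom, pmax(peaks$anchor - flank, 0L),
                  peaks$anchor + flank, name = peaks$name)
  hits <- overlap_pairs(win, marks, min_overlap = 1L)
  seq_len(nrow(peaks)) %in% hits$query
}

#' Regulatory-state rule table
#'
#' Maps the three mark-presence booleans to one of five candidate
#' regulatory element states.  The rules follow the standard chromatin
#' vocabulary: H3K27ac together with the promoter mark H3K4me3 denotes a
#' candidate active promoter (`cAP`; the promoter mark dominates when all
#' three marks co-occur); H3K27ac with H3K4me1 but without H3K4me3 a
#' candidate active enhancer (`cAE`); H3K4me3 without H3K27ac a candidate
#' inactive promoter (`cIP`); H3K4me1 alone a candidate inactive enhancer
#' (`cIE`); anything else, including H3K27ac with neither methyl mark,
#' `other`.  The function is total and deterministic on the 8 boolean
#' combinations.
#'
#' @param h3k27ac,h3k4me1,h3k4me3 logical vectors of equal length.
#' @return Character vector of states in
#'   `c("cAP", "cAE", "cIP", "cIE", "other")`.
#' @export
classify_regulatory_state <- function(h3k27ac, h3k4me1, h3k4me3) {
  stopifnot(length(h3k27ac) == length(h3k4me1),
            length(h3k27ac) == length(h3k4me3))
  ifelse(h3k27ac & h3k4me3, "cAP",
    ifelse(h3k27ac & h3k4me1, "cAE",
      ifelse(!h3k27ac & h3k4me3, "cIP",
        ifelse(!h3k27ac & h3k4me1, "cIE", "other"))))
}

#' Open-chromatin flag
#'
#' A peak is in open chromatin when its full interval overlaps any
#' ATAC-seq interval by at least 1 bp.
#'
#' @param peaks a [peak_set()].
#' @param atac a [peak_set()] of open-chromatin intervals.
#' @return Logical vector along `peaks`.
#' @export
open_chromatin_flag <- function(peaks, atac) {
  if (nrow(peaks) == 0L) return(logical(0))
  if (nrow(atac) == 0L) return(rep(FALSE, nrow(peaks)))
  hits <- overlap_pairs(peaks, atac, min_overlap = 1L)
  seq_len(nrow(peaks)) %in% hits$query
}

#' Classify peaks into candidate regulatory element states
#'
#' Convenience wrapper combining [mark_presence()] for the three histone
#' marks, [classify_regulatory_state()] and [open_chromatin_flag()].
#'
#' @param peaks a [peak_set()].
#' @param h3k27ac,h3k4me1,h3k4me3 [peak_set()]s of mark intervals.
#' @param atac optional [peak_set()] of ATAC intervals (all-`FALSE` flags
#'   when `NULL`).
#' @param flank half-window for mark presence in bp (default 1000).
#' @return A `data.frame` with `peak_name`, the three mark booleans,
#'   `state` and `open_chromatin`.
#' @export
classify_chromatin_states <- function(peaks, h3k27ac, h3k4me1, h3k4me3,
                                      atac = NULL, flank = 1000L) {
  ac <- mark_presence(peaks, h3k27ac, flank)
  me1 <- mark_presence(peaks, h3k4me1, flank)
  me3 <- mark_presence(peaks, h3k4me3, flank)
  open <- if (is.null(atac)) rep(FALSE, nrow(peaks)) else
    open_chromatin_flag(peaks, atac)
  data.frame(peak_name = peaks$name,
             H3K27ac = ac, H3K4me1 = me1, H3K4me3 = me3,
             state = classify_regulatory_state(ac, me1, me3),
             open_chromatin = open,
             stringsAsFactors = FALSE)
}

#' Per-state summary of a regulatory classification
#'
#' @param classifications output of [classify_chromatin_states()].
#' @return A `data.frame` with one row per state: `state`, `count`,
#'   `fraction` (summing to 1) and `open_fraction` (fraction of the
#'   state's peaks flagged open; `NA` for empty states).
#' @export
state_summary <- function(classifications) {
  if (nrow(classifications) == 0L) stop("empty classification table")
  lev <- c("cAP", "cAE", "cIP", "cIE", "other")
  st <- factor(classifications$state, levels = lev)
  counts <- table(st)
  open <- tapply(classifications$open_chromatin, st, mean)
  data.frame(state = lev, count = as.integer(counts),
             fraction = as.numeric(counts) / nrow(classifications),
             open_fraction = as.numeric(open),
             stringsAsFactors = FALSE)
}

#' Heatmap of a binned signal matrix
#'
#' Draws the peaks x bins matrix with rows sorted by decreasing total
#' signal, the conventional presentation for mark occupancy around binding
#' sites.  Uses `pheatmap` when available, otherwise base `image()`.
#'
#' @param mat matrix from [bin_signal()].
#' @param main plot title.
#' @return Invisibly, the row order used.
#' @export
plot_signal_heatmap <- function(mat, main = attr(mat, "mark_name")) {
  ord <- order(rowSums(mat), decreasing = TRUE)
  m <- mat[ord, , drop = FALSE]
  if (requireNamespace("pheatmap", quietly = TRUE)) {
    pheatmap::pheatmap(m, cluster_rows = FALSE, cluster_cols = FALSE,
                       show_rownames = FALSE, main = main)
  } else {
    graphics::image(t(m[rev(seq_len(nrow(m))), , drop = FALSE]),
                    axes = FALSE, main = main)
  }
  invisible(ord)
}
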
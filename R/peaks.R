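#' Peak sets
#'
#' A peak set is a plain `data.frame` with one row per peak and columns
#' `chrom`, `start`, `end` (0-based half-open, BED convention), `name`,
#' `score`, `strand`, `summit_offset` (offset of the point source from
#' `start`, `NA` when absent) and `anchor` (the derived point used for
#' distances and binning: `start + summit_offset` when a summit is known,
#' otherwise the interval midpoint `floor((start + end) / 2)`).
#'
#' All coordinates are kept 0-based half-open internally; 1-based formats
#' (GTF) are converted at the reader boundary.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors, 0-based half-open; `start < end`.
#' @param name peak identifiers; auto-generated as `chrom:start-end` when
#'   missing. Must be unique within a set.
#' @param score optional numeric score.
#' @param strand one of `"+"`, `"-"`, `"."`.
#' @param summit_offset integer offset of the summit from `start`, or `NA`.
#' @param source_label label describing the origin of the set.
#' @return A `data.frame` of class `peak_set`.
#' @examples
#' peak_set("chr1", 100, 200, summit_offset = 30)
#' @export
peak_set <- function(chrom, start, end, name = NULL, score = NA_real_,
                     strand = ".", summit_offset = NA_integer_,
                     source_label = "peaks") {
  start <- as.integer(start)
  end <- as.integer(end)
  n <- max(length(chrom), length(start))
  chrom <- rep_len(as.character(chrom), n)
  if (length(start) != n || length(end) != n) {
    stop("start and end must have length ", n)
  }
  if (any(start < 0L)) stop("peak start must be >= 0")
  if (any(start >= end)) {
    bad <- which(start >= end)[1L]
    stop(sprintf("invalid interval at record %d: start (%d) >= end (%d)",
                 bad, start[bad], end[bad]))
  }
  if (is.null(name)) name <- rep(NA_character_, n)
  name <- as.character(name)
  auto <- is.na(name) | name == "" | name == "."
  name[auto] <- sprintf("%s:%d-%d", chrom[auto], start[auto], end[auto])
  if (anyDuplicated(name)) {
    name <- make.unique(name, sep = "_dup")
  }
  summit_offset <- as.integer(summit_offset)
  if (length(summit_offset) == 1L) summit_offset <- rep(summit_offset, n)
  ok <- is.na(summit_offset) |
    (summit_offset >= 0L & summit_offset < end - start)
  if (!all(ok)) {
    stop(sprintf("summit offset out of range for peak '%s'",
                 name[which(!ok)[1L]]))
  }
  anchor <- ifelse(is.na(summit_offset),
                   (start + end) %/% 2L,
                   start + summit_offset)
  ps <- data.frame(chrom = chrom, start = start, end = end,
                   name = name,
                   score = rep_len(as.numeric(score), n),
                   strand = rep_len(as.character(strand), n),
                   summit_offset = summit_offset,
                   anchor = as.integer(anchor),
                   stringsAsFactors = FALSE)
  attr(ps, "source_label") <- source_label
  class(ps) <- c("peak_set", "data.frame")
  ps
}

#' @rdname peak_set
#' @export
empty_peak_set <- function(source_label = "peaks") {
  ps <- data.frame(chrom = character(), start = integer(), end = integer(),
                   name = character(), score = numeric(), strand = character(),
                   summit_offset = integer(), anchor = integer(),
                   stringsAsFactors = FALSE)
  attr(ps, "source_label") <- source_label
  class(ps) <- c("peak_set", "data.frame")
  ps
}

#' Read peaks from BED or narrowPeak files
#'
#' Reads BED3/BED6 or ENCODE narrowPeak (BED6+4) files into a [peak_set()].
#' narrowPeak column 10 (point-source offset) is mapped to `summit_offset`;
#' the sentinel value -1 means "no summit" and yields a midpoint anchor.
#' Lines starting with `#`, `track` or `browser` are skipped.
#'
#' @param path path to a tab-separated BED-family file.
#' @param format `"bed"` or `"narrowpeak"` (`"auto"` picks narrowPeak when
#'   the file has 10 columns).
#' @param source_label label stored on the returned set; defaults to the
#'   file name.
#' @return A [peak_set()].
#' @export
read_peaks <- function(path, format = c("auto", "bed", "narrowpeak"),
                       source_label = basename(path)) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) return(empty_peak_set(source_label))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (format == "auto") format <- if (all(nf == 10L)) "narrowpeak" else "bed"
  need <- if (format == "narrowpeak") 10L else 3L
  if (any(nf < need)) {
    bad <- which(nf < need)[1L]
    stop(sprintf("malformed %s line %d in '%s': %d field(s), expected >= %d",
                 format, lineno[bad], path, nf[bad], need))
  }
  col <- function(i) vapply(fields, `[`, character(1), i)
  num <- function(x, what, i) {
    v <- suppressWarnings(as.numeric(x))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1L]
      stop(sprintf("malformed line %d in '%s': non-numeric %s '%s'",
                   lineno[bad], path, what, x[bad]))
    }
    v
  }
  chrom <- col(1)
  start <- num(col(2), "start", 2)
  end <- num(col(3), "end", 3)
  if (any(start >= end)) {
    bad <- which(start >= end)[1L]
    stop(sprintf("invalid interval at line %d in '%s': start >= end",
                 lineno[bad], path))
  }
  name <- if (all(nf >= 4L)) col(4) else NULL
  score <- if (all(nf >= 5L)) num(col(5), "score", 5) else NA_real_
  strand <- if (all(nf >= 6L)) col(6) else "."
  summit <- NA_integer_
  extra <- NULL
  if (format == "narrowpeak") {
    summit <- as.integer(num(col(10), "summit offset", 10))
    summit[summit < 0L] <- NA_integer_
    extra <- data.frame(signal_value = num(col(7), "signalValue", 7),
                        p_value = num(col(8), "pValue", 8),
                        q_value = num(col(9), "qValue", 9))
  }
  ps <- peak_set(chrom, start, end, name = name, score = score,
                 strand = strand, summit_offset = summit,
                 source_label = source_label)
  if (!is.null(extra)) {
    ps$signal_value <- extra$signal_value
    ps$p_value <- extra$p_value
    ps$q_value <- extra$q_value
  }
  ps
}

#' Write peaks to BED or narrowPeak files
#'
#' Round-trip guarantee: `read_peaks(write_peaks(x))` reproduces
#' coordinates, names and summit offsets exactly.
#'
#' @param peaks a [peak_set()].
#' @param path output path.
#' @param format `"bed"` (6 columns) or `"narrowpeak"` (10 columns).
#' @return `path`, invisibly.
#' @export
write_peaks <- function(peaks, path, format = c("narrowpeak", "bed")) {
  format <- match.arg(format)
  score <- ifelse(is.na(peaks$score), 0, peaks$score)
  strand <- ifelse(is.na(peaks$strand) | peaks$strand == "", ".",
                   peaks$strand)
  df <- data.frame(peaks$chrom, peaks$start, peaks$end, peaks$name,
                   score, strand)
  if (format == "narrowpeak") {
    n <- nrow(peaks)
    sv <- if ("signal_value" %in% names(peaks)) peaks$signal_value else
      rep(0, n)
    pv <- if ("p_value" %in% names(peaks)) peaks$p_value else rep(-1, n)
    qv <- if ("q_value" %in% names(peaks)) peaks$q_value else rep(-1, n)
    summit <- ifelse(is.na(peaks$summit_offset), -1L, peaks$summit_offset)
    df <- cbind(df, sv, pv, qv, summit)
  }
  ok <- tryCatch({
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("failed to write '", path, "': ",
                        conditionMessage(ok))
  invisible(path)
}

# IRanges view of a peak set (1-based closed, the IRanges convention)
peak_ranges <- function(peaks) {
  IRanges::IRanges(start = peaks$start + 1L, end = peaks$end)
}

# overlap widths >= min_overlap between two peak sets, chromosome-aware;
# returns hits as a data.frame(query, subject)
overlap_pairs <- function(a, b, min_overlap = 1L) {
  if (nrow(a) == 0L || nrow(b) == 0L) {
    return(data.frame(query = integer(), subject = integer()))
  }
  lv <- union(a$chrom, b$chrom)  # shared seqlevels: quiet, order-stable
  hits <- GenomicRanges::findOverlaps(
    GenomicRanges::GRanges(factor(a$chrom, levels = lv), peak_ranges(a)),
    GenomicRanges::GRanges(factor(b$chrom, levels = lv), peak_ranges(b)),
    minoverlap = as.integer(min_overlap))
  data.frame(query = S4Vectors::queryHits(hits),
             subject = S4Vectors::subjectHits(hits))
}

#' Intersect replicate peak sets
#'
#' Returns the peaks of `rep1` that overlap at least one peak of `rep2` by
#' at least `min_overlap` bp (half-open overlap
#' `max(0, min(b, d) - max(a, c))`), the standard definition of binding
#' sites reproducible across biological replicates.  Coordinates are taken
#' from `rep1` by default; `mode = "merge-union"` returns the union span of
#' each rep1 peak with its overlapping rep2 peaks, `"merge-intersection"`
#' the intersection span with the nearest-overlapping rep2 peak.  Each rep1
#' peak is counted once however many rep2 peaks it overlaps.
#'
#' @param rep1,rep2 [peak_set()] objects.
#' @param min_overlap minimum overlap in bp (default 1).
#' @param mode coordinate policy for retained peaks.
#' @return A [peak_set()], a subset of `rep1` in `rep1` order.
#' @export
intersect_replicates <- function(rep1, rep2, min_overlap = 1L,
                                 mode = c("rep1", "merge-union",
                                          "merge-intersection")) {
  mode <- match.arg(mode)
  if (min_overlap < 1L) stop("min_overlap must be >= 1")
  hits <- overlap_pairs(rep1, rep2, min_overlap)
  idx <- sort(unique(hits$query))
  out <- rep1[idx, , drop = FALSE]
  if (mode != "rep1" && nrow(out) > 0L) {
    for (k in seq_along(idx)) {
      i <- idx[k]
      js <- hits$subject[hits$query == i]
      if (mode == "merge-union") {
        out$start[k] <- min(out$start[k], min(rep2$start[js]))
        out$end[k] <- max(out$end[k], max(rep2$end[js]))
      } else {
        widths <- pmin(out$end[k], rep2$end[js]) -
          pmax(out$start[k], rep2$start[js])
        j <- js[which.max(widths)]
        out$start[k] <- max(out$start[k], rep2$start[j])
        out$end[k] <- min(out$end[k], rep2$end[j])
      }
    }
    # summit may fall outside merged coordinates; re-derive anchors
    off <- out$summit_offset
    bad <- !is.na(off) & (off < 0L | off >= out$end - out$start)
    off[bad] <- NA_integer_
    out$summit_offset <- off
    out$anchor <- as.integer(ifelse(is.na(off), (out$start + out$end) %/% 2L,
                                    out$start + off))
  }
  rownames(out) <- NULL
  attr(out, "source_label") <- attr(rep1, "source_label")
  class(out) <- c("peak_set", "data.frame")
  out
}
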
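DNA <- c("A", "C", "G", "T")

#' Build a position weight matrix
#'
#' Converts a position frequency matrix (counts) into probabilities and a
#' log-odds scoring matrix against a 0-order background.  Column
#' probabilities are `(count + pseudocount * background) / (colsum +
#' pseudocount)` so every cell stays positive, and the score of base `b`
#' at position `j` is `log2(prob[b, j] / background[b])` in bits.
#'
#' @param counts 4 x width non-negative matrix, rows in A, C, G, T order
#'   (row names are honoured when present).
#' @param name motif name.
#' @param pseudocount total pseudocount mass added per column,
#'   distributed by the background (default 0.1).
#' @param background length-4 probability vector (A, C, G, T); must be
#'   strictly positive and is renormalized to sum to 1.
#' @return An object of class `pwm`: a list with `name`, `width`,
#'   `counts`, `pseudocount`, `background`, `prob` and `log_odds`.
#' @examples
#' pfm <- matrix(c(0, 0, 0, 100), nrow = 4,
#'               dimnames = list(c("A", "C", "G", "T"), NULL))
#' build_pwm(pfm, "T1", pseudocount = 0.25)
#' @export
build_pwm <- function(counts, name = "motif", pseudocount = 0.1,
                      background = rep(0.25, 4)) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4L) stop("counts must have 4 rows (A, C, G, T)")
  if (!is.null(rownames(counts))) {
    if (!setequal(rownames(counts), DNA)) {
      stop("counts row names must be A, C, G, T")
    }
    counts <- counts[DNA, , drop = FALSE]
  } else {
    rownames(counts) <- DNA
  }
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(colSums(counts) == 0)) stop("all-zero column in frequency matrix")
  if (pseudocount <= 0) stop("pseudocount must be positive")
  if (length(background) != 4L) stop("background must have 4 entries")
  if (any(background <= 0)) stop("background entries must be positive")
  background <- background / sum(background)
  names(background) <- DNA
  adj <- counts + pseudocount * background
  prob <- sweep(adj, 2, colSums(adj), "/")
  log_odds <- log2(prob / background)
  structure(list(name = name, width = ncol(counts), counts = counts,
                 pseudocount = pseudocount, background = background,
                 prob = prob, log_odds = log_odds),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("PWM '%s': width %d, consensus %s\n",
              x$name, x$width, pwm_consensus(x)))
  invisible(x)
}

IUPAC <- c(A = "A", C = "C", G = "G", T = "T",
           AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K",
           ACG = "V", ACT = "H", AGT = "D", CGT = "B", ACGT = "N")

#' Consensus string of a PWM
#'
#' Per column, all bases whose probability is within two-fold of the
#' column maximum are collapsed into one IUPAC symbol.
#'
#' @param pwm a [build_pwm()] object.
#' @return A character scalar of length `width`.
#' @export
pwm_consensus <- function(pwm) {
  paste(apply(pwm$prob, 2, function(p) {
    keep <- DNA[p >= max(p) / 2]
    IUPAC[[paste(keep, collapse = "")]]
  }), collapse = "")
}

#' Read JASPAR-style position frequency matrices
#'
#' Parses the JASPAR PFM text format: an optional `>identifier name`
#' header followed by four rows of counts in A, C, G, T order, with or
#' without row labels and brackets (`A [ 1 2 3 ]`).  Several motifs per
#' file are supported.
#'
#' @param path path to a PFM text file.
#' @return A named list of 4 x width count matrices.
#' @export
read_pfm <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  out <- list()
  name <- NULL
  rows <- list()
  flush <- function() {
    if (length(rows) == 0L) return()
    if (length(rows) != 4L) {
      stop("motif '", name %||% "(unnamed)", "' in '", path,
           "' has ", length(rows), " rows, expected 4")
    }
    w <- unique(lengths(rows))
    if (length(w) != 1L) stop("ragged PFM rows for motif '", name, "'")
    m <- do.call(rbind, rows)
    rownames(m) <- DNA
    out[[name %||% paste0("motif", length(out) + 1L)]] <<- m
    rows <<- list()
  }
  for (ln in lines) {
    if (startsWith(ln, ">")) {
      flush()
      name <- strsplit(sub("^>\\s*", "", ln), "\\s+")[[1]][1]
      next
    }
    body <- sub("^[ACGTacgt][:]?\\s*", "", ln)
    body <- gsub("[][]", " ", body)
    vals <- suppressWarnings(as.numeric(strsplit(trimws(body), "\\s+")[[1]]))
    if (anyNA(vals)) stop("malformed PFM row in '", path, "': ", ln)
    rows[[length(rows) + 1L]] <- vals
  }
  flush()
  if (length(out) == 0L) stop("no motifs found in '", path, "'")
  out
}

#' Read MEME minimal-format motifs
#'
#' Parses the MEME minimal motif format (`MOTIF` blocks with a
#' `letter-probability matrix` whose rows list A, C, G, T probabilities
#' per position).  Probabilities are scaled by the recorded `nsites`
#' (default 100) to recover pseudo-counts.
#'
#' @param path path to a MEME minimal file.
#' @return A named list of 4 x width count matrices.
#' @export
read_meme <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- trimws(readLines(path))
  out <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (grepl("^MOTIF\\b", lines[i])) {
      name <- strsplit(lines[i], "\\s+")[[1]][2]
      j <- i + 1L
      while (j <= length(lines) &&
             !grepl("^letter-probability matrix", lines[j])) j <- j + 1L
      if (j > length(lines)) stop("MOTIF '", name, "' has no matrix")
      hdr <- lines[j]
      w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", hdr))
      ns <- if (grepl("nsites=", hdr)) {
        as.numeric(sub(".*nsites=\\s*([0-9.]+).*", "\\1", hdr))
      } else 100
      rows <- lines[(j + 1L):(j + w)]
      m <- t(vapply(rows, function(r) {
        as.numeric(strsplit(r, "\\s+")[[1]][1:4])
      }, numeric(4)))
      m <- t(m) * ns
      rownames(m) <- DNA
      out[[name]] <- m
      i <- j + w + 1L
    } else {
      i <- i + 1L
    }
  }
  if (length(out) == 0L) stop("no motifs found in '", path, "'")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Exact score distribution of a PWM under its background
#'
#' Convolves the per-column score distributions exactly over the lattice
#' of achievable log-odds sums, giving the exact null distribution of the
#' score of a width-length string drawn from the 0-order background.
#' Column scores are snapped to a 1e-9-bit grid so the convolution runs
#' on exact integer keys (no floating-point drift across columns); scores
#' within 1e-7 bits are treated as equal throughout.  Refuses with an
#' advisory when the lattice would exceed `max_states` support points
#' (very wide, near-continuous matrices), rather than silently losing
#' accuracy.
#'
#' @param pwm a [build_pwm()] object.
#' @param max_states cap on the support size (default 2^20).
#' @return A list with sorted `score`, point `prob`, and `pval`
#'   (`P(S >= score)`).
#' @export
score_distribution <- function(pwm, max_states = 2^20) {
  keys <- 0   # integer multiples of 1e-9 bits, exact in doubles
  probs <- 1
  for (j in seq_len(pwm$width)) {
    colkey <- round(pwm$log_odds[, j] * 1e9)
    k <- as.vector(outer(keys, colkey, `+`))
    p <- as.vector(outer(probs, pwm$background, `*`))
    agg <- rowsum(p, k)
    keys <- as.numeric(rownames(agg))
    probs <- as.vector(agg)
    if (length(keys) > max_states) {
      stop("score lattice of PWM '", pwm$name, "' exceeds ", max_states,
           " support points; exact p-values refused -- reduce the motif ",
           "width or raise max_states")
    }
  }
  ord <- order(keys)
  scores <- keys[ord] / 1e9
  probs <- probs[ord]
  list(score = scores, prob = probs, pval = rev(cumsum(rev(probs))))
}

#' Exact p-value of a PWM score
#'
#' `P(S >= score)` for the log-odds score `S` of a random width-length
#' string drawn from the PWM's 0-order background, computed from the
#' exact score distribution.  Scores within 1e-7 bits of a support point
#' count as attaining it.  Monotone non-increasing in `score`;
#' `P(S >= min score) = 1`.
#'
#' @param pwm a [build_pwm()] object.
#' @param score numeric vector of scores in bits.
#' @param dist optional precomputed [score_distribution()].
#' @return Numeric vector of tail probabilities.
#' @export
exact_score_pvalue <- function(pwm, score, dist = NULL) {
  if (any(!is.finite(score))) {
    if (any(is.na(score) | is.nan(score))) stop("score must be finite")
  }
  if (is.null(dist)) dist <- score_distribution(pwm)
  tailp <- c(dist$pval, 0)
  i <- findInterval(score - 1e-7, dist$score, left.open = TRUE)
  pmin(tailp[i + 1L], 1)
}

# smallest score whose exact p-value is <= threshold_p; Inf when none
.threshold_score <- function(dist, threshold_p) {
  i <- which(dist$pval <= threshold_p)
  if (length(i) == 0L) Inf else dist$score[min(i)]
}

.encode_dna <- function(seq) {
  code <- match(strsplit(toupper(seq), "")[[1]], DNA)  # N and others -> NA
  code
}

# scores of all windows of length w; NA where the window contains a non-ACGT
.window_scores <- function(code, lo) {
  w <- ncol(lo)
  nw <- length(code) - w + 1L
  if (nw <= 0L) return(numeric(0))
  s <- numeric(nw)
  for (p in seq_len(w)) {
    s <- s + lo[cbind(code[p:(p + nw - 1L)], p)]
  }
  s
}

#' Scan a DNA sequence with a PWM
#'
#' Scores every window of `width` positions on both strands with the
#' log-odds matrix (the minus-strand score is the score of the window's
#' reverse complement) and reports windows whose exact background p-value
#' is at most `threshold_p`.  Windows containing `N` are skipped.  All
#' overlapping hits are reported; hits are sorted by offset, then strand.
#'
#' @param seq DNA string over `A,C,G,T,N` (case-insensitive).
#' @param pwm a [build_pwm()] object.
#' @param threshold_p p-value threshold in `(0, 1)` (default 1e-4, the
#'   FIMO default).
#' @param dist optional precomputed [score_distribution()] for `pwm`.
#' @return A `data.frame` of hits: `offset` (0-based from sequence start),
#'   `strand`, `score` (bits) and `pvalue`.
#' @export
scan_sequence <- function(seq, pwm, threshold_p = 1e-4, dist = NULL) {
  stopifnot(threshold_p > 0, threshold_p < 1)
  if (is.null(dist)) dist <- score_distribution(pwm)
  empty <- data.frame(offset = integer(), strand = character(),
                      score = numeric(), pvalue = numeric(),
                      stringsAsFactors = FALSE)
  code <- .encode_dna(seq)
  if (length(code) < pwm$width) return(empty)
  lo <- pwm$log_odds
  lo_rc <- lo[4:1, rev(seq_len(ncol(lo))), drop = FALSE]
  smin <- .threshold_score(dist, threshold_p)
  res <- empty
  for (str in c("+", "-")) {
    sc <- .window_scores(code, if (str == "+") lo else lo_rc)
    hit <- which(!is.na(sc) & sc >= smin - 1e-7)
    if (length(hit)) {
      res <- rbind(res, data.frame(
        offset = hit - 1L, strand = str, score = sc[hit],
        pvalue = exact_score_pvalue(pwm, sc[hit], dist),
        stringsAsFactors = FALSE))
    }
  }
  res <- res[order(res$offset, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Extract peak sequences from a genome
#'
#' @param peaks a [peak_set()].
#' @param genome a `Biostrings::DNAStringSet` named by chromosome, or a
#'   path to a FASTA file.
#' @return Named character vector of peak sequences.
#' @export
peak_sequences <- function(peaks, genome) {
  if (is.character(genome) && length(genome) == 1L) {
    genome <- Biostrings::readDNAStringSet(genome)
    names(genome) <- sub("\\s.*$", "", names(genome))
  }
  seqs <- character(nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    chr <- peaks$chrom[i]
    if (!chr %in% names(genome)) {
      stop("peak '", peaks$name[i], "': chromosome '", chr,
           "' absent from genome")
    }
    if (peaks$end[i] > length(genome[[chr]])) {
      stop("peak '", peaks$name[i], "' extends past the end of ", chr)
    }
    seqs[i] <- as.character(Biostrings::subseq(genome[[chr]],
                                               peaks$start[i] + 1L,
                                               peaks$end[i]))
  }
  names(seqs) <- peaks$name
  seqs
}

#' Motif occurrence fractions over a peak set
#'
#' Scans every peak sequence with each PWM and reports, per motif, the
#' fraction of peaks carrying at least one hit at the p-value threshold.
#' Unless a background is supplied, the 0-order background is estimated
#' from the scanned sequences themselves and the PWMs are rebuilt against
#' it (FIMO-like behaviour).
#'
#' @param peaks a [peak_set()].
#' @param genome a `DNAStringSet` or FASTA path.
#' @param pwms named list of [build_pwm()] objects (or raw 4 x width count
#'   matrices).
#' @param threshold_p p-value threshold (default 1e-4).
#' @param background optional length-4 background probability vector; when
#'   `NULL`, estimated from the peak sequences.
#' @return A list: `summary` (data.frame `motif`, `n_peaks_with_hit`,
#'   `fraction`), `per_peak` (logical peaks x motifs matrix) and `hits`
#'   (all hits with peak names).
#' @export
peak_motif_fractions <- function(peaks, genome, pwms, threshold_p = 1e-4,
                                 background = NULL) {
  if (length(pwms) == 0L) {
    return(list(summary = data.frame(motif = character(),
                                     n_peaks_with_hit = integer(),
                                     fraction = numeric()),
                per_peak = matrix(FALSE, nrow(peaks), 0,
                                  dimnames = list(peaks$name, NULL)),
                hits = NULL))
  }
  seqs <- peak_sequences(peaks, genome)
  if (is.null(background)) {
    tab <- table(factor(unlist(strsplit(toupper(paste(seqs, collapse = "")),
                                        "")), levels = DNA))
    background <- as.numeric(tab) / sum(tab)
    if (any(background == 0)) background <- (as.numeric(tab) + 1) /
        (sum(tab) + 4)
  }
  pwms <- lapply(seq_along(pwms), function(k) {
    p <- pwms[[k]]
    nm <- names(pwms)[k] %||% paste0("motif", k)
    if (inherits(p, "pwm")) {
      build_pwm(p$counts, p$name, p$pseudocount, background)
    } else {
      build_pwm(p, nm, background = background)
    }
  })
  names(pwms) <- vapply(pwms, `[[`, character(1), "name")
  per_peak <- matrix(FALSE, nrow(peaks), length(pwms),
                     dimnames = list(peaks$name, names(pwms)))
  hits <- list()
  for (m in names(pwms)) {
    dist <- score_distribution(pwms[[m]])
    for (i in seq_along(seqs)) {
      h <- scan_sequence(seqs[i], pwms[[m]], threshold_p, dist)
      if (nrow(h) > 0L) {
        per_peak[i, m] <- TRUE
        h <- cbind(peak_name = peaks$name[i], motif = m, h,
                   stringsAsFactors = FALSE)
        hits[[length(hits) + 1L]] <- h
      }
    }
  }
  hits <- if (length(hits)) do.call(rbind, hits) else
    data.frame(peak_name = character(), motif = character(),
               offset = integer(), strand = character(),
               score = numeric(), pvalue = numeric())
  list(summary = data.frame(motif = colnames(per_peak),
                            n_peaks_with_hit = colSums(per_peak),
                            fraction = colMeans(per_peak),
                            row.names = NULL,
                            stringsAsFactors = FALSE),
       per_peak = per_peak,
       hits = hits)
}
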
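#' Rank genes by a signed metric
#'
#' Sorts a named metric vector (typically log2 fold change) in decreasing
#' order; ties are broken deterministically by gene id, and duplicate
#' gene ids are an error.
#'
#' @param metric named numeric vector.
#' @return The sorted named vector.
#' @export
rank_genes <- function(metric) {
  if (is.null(names(metric)) || any(!nzchar(names(metric)))) {
    stop("metric must be named by gene id")
  }
  if (anyDuplicated(names(metric))) stop("duplicated gene ids in metric")
  metric[order(-metric, names(metric))]
}

#' Weighted running-sum enrichment score
#'
#' Walks the ranked list from top to bottom, incrementing by
#' `|metric|^weight_p / N_R` at gene-set members (where `N_R` is the sum
#' of `|metric|^weight_p` over members) and decrementing by
#' `1 / (N - N_hits)` elsewhere.  The enrichment score is the value of
#' the running sum at its maximal absolute deviation from zero, keeping
#' its sign.  With `weight_p = 0` this is the classical Kolmogorov-
#' Smirnov-like statistic.
#'
#' @param ranked named metric vector; re-sorted with [rank_genes()]
#'   internally so callers can pass unsorted vectors.
#' @param gene_set character vector of member gene ids; at least one must
#'   be present in the list and not all genes may be members.
#' @param weight_p non-negative weighting exponent (default 1).
#' @return A list: `es`, `running_sum` (length-N numeric), `hit_positions`
#'   (ranks of the members), `n_hits`.
#' @export
enrichment_score <- function(ranked, gene_set, weight_p = 1) {
  stopifnot(weight_p >= 0)
  ranked <- rank_genes(ranked)
  member <- names(ranked) %in% gene_set
  n <- length(ranked)
  nh <- sum(member)
  if (nh == 0L) stop("no gene of the set is present in the ranked list")
  if (nh == n) stop("gene set covers the whole list (degenerate)")
  w <- abs(ranked)^weight_p
  w[!member] <- 0
  nr <- sum(w)
  inc <- if (nr > 0) w / nr else member / nh  # all-zero metric fallback
  dec <- (!member) / (n - nh)
  running <- unname(cumsum(inc - dec))
  i <- which.max(abs(running))
  list(es = running[i], running_sum = running,
       hit_positions = which(member), n_hits = nh)
}

# ES for a membership position vector over precomputed |metric|^p
.es_positions <- function(absw, pos, n) {
  nh <- length(pos)
  inc <- numeric(n)
  wr <- absw[pos]
  nr <- sum(wr)
  inc[pos] <- if (nr > 0) wr / nr else 1 / nh
  dec <- rep(1 / (n - nh), n)
  dec[pos] <- 0
  running <- cumsum(inc - dec)
  running[which.max(abs(running))]
}

#' Preranked gene-set enrichment with permutation normalization
#'
#' Computes the enrichment score of each gene set on the ranked list and
#' builds its null distribution from random gene sets of identical size
#' drawn without replacement from the list (gene-set permutation, the
#' null model appropriate when only a preranked list exists).  The
#' normalized score is `NES = ES / mean(|null ES| of the same sign)` and
#' the p-value is `(1 + #{same-sign null ES at least as extreme}) /
#' (1 + #{same-sign null ES})`, both sign-stratified as in the original
#' method.  A simple sign-stratified empirical FDR over the tested
#' collection is reported alongside.  Results are deterministic given
#' `seed`.
#'
#' @param ranked named metric vector (resorted internally).
#' @param gene_sets named list of character vectors.
#' @param n_perm number of permutations, `>= 100` (default 1000).
#' @param weight_p weighting exponent (default 1).
#' @param seed integer seed (required).
#' @return A `data.frame` with one row per set: `set_name`, `es`, `nes`,
#'   `pvalue`, `fdr`, `n_hits` and `null_degenerate` (no same-sign null
#'   score existed; `pvalue` reported as 1).
#' @export
gsea_prerank <- function(ranked, gene_sets, n_perm = 1000, weight_p = 1,
                         seed) {
  if (missing(seed)) stop("a seed is required for reproducibility")
  if (n_perm < 100) stop("n_perm must be >= 100")
  ranked <- rank_genes(ranked)
  n <- length(ranked)
  absw <- abs(ranked)^weight_p
  set.seed(as.integer(seed))
  rows <- vector("list", length(gene_sets))
  null_pos <- list()
  null_neg <- list()
  for (k in seq_along(gene_sets)) {
    res <- enrichment_score(ranked, gene_sets[[k]], weight_p)
    nh <- res$n_hits
    null_es <- vapply(seq_len(n_perm), function(b) {
      .es_positions(absw, sample.int(n, nh), n)
    }, numeric(1))
    same <- null_es[sign(null_es) == sign(res$es)]
    degenerate <- length(same) == 0L
    nes <- if (degenerate) NA_real_ else res$es / mean(abs(same))
    pval <- if (degenerate) 1 else
      (1 + sum(abs(same) >= abs(res$es))) / (1 + length(same))
    null_nes <- if (degenerate) numeric(0) else null_es / mean(abs(same))
    if (!degenerate && res$es >= 0) {
      null_pos[[length(null_pos) + 1L]] <- null_nes[null_nes >= 0]
    } else if (!degenerate) {
      null_neg[[length(null_neg) + 1L]] <- null_nes[null_nes < 0]
    }
    rows[[k]] <- data.frame(set_name = names(gene_sets)[k] %||%
                              paste0("set", k),
                            es = res$es, nes = nes, pvalue = pval,
                            n_hits = nh, null_degenerate = degenerate,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  # sign-stratified empirical FDR over the collection
  pool_pos <- unlist(null_pos)
  pool_neg <- unlist(null_neg)
  out$fdr <- NA_real_
  for (k in seq_len(nrow(out))) {
    if (is.na(out$nes[k])) next
    if (out$nes[k] >= 0) {
      obs <- out$nes[!is.na(out$nes) & out$nes >= 0]
      num <- if (length(pool_pos)) mean(pool_pos >= out$nes[k]) else 0
      den <- mean(obs >= out$nes[k])
    } else {
      obs <- out$nes[!is.na(out$nes) & out$nes < 0]
      num <- if (length(pool_neg)) mean(pool_neg <= out$nes[k]) else 0
      den <- mean(obs <= out$nes[k])
    }
    out$fdr[k] <- min(1, num / den)
  }
  out[, c("set_name", "es", "nes", "pvalue", "fdr", "n_hits",
          "null_degenerate")]
}

#' Read gene sets from a GMT file
#'
#' @param path path to a GMT file (tab-separated: set name, description,
#'   then member genes).
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- lapply(strsplit(lines, "\t", fixed = TRUE), function(f) {
    if (length(f) < 3L) stop("malformed GMT line: ", f[1])
    unique(f[-(1:2)])
  })
  names(sets) <- vapply(strsplit(lines, "\t", fixed = TRUE), `[`,
                        character(1), 1)
  sets
}

#' Read a two-column ranked list (RNK)
#'
#' @param path path to a tab-separated file: gene id, metric.
#' @return Named numeric vector sorted by decreasing metric.
#' @export
read_rnk <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE,
                          col.names = c("gene_id", "metric"))
  rank_genes(stats::setNames(df$metric, df$gene_id))
}
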
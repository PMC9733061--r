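# Independent brute-force oracles and small random-fixture generators.
# These deliberately re-derive every rule with plain loops, not via the
# package's own code paths.

rand_peaks <- function(n, chrom_len = 100000L, chroms = "chrA",
                       min_w = 20L, max_w = 500L) {
  chrom <- sample(chroms, n, replace = TRUE)
  w <- sample(min_w:max_w, n, replace = TRUE)
  start <- vapply(w, function(wi) sample.int(chrom_len - wi, 1L) - 1L,
                  integer(1))
  peak_set(chrom, start, start + w, name = sprintf("p%04d", seq_len(n)))
}

rand_genes <- function(n, chrom_len = 200000L, chroms = "chrA") {
  len <- sample(500:5000, n, replace = TRUE)
  start <- vapply(len, function(l) sample.int(chrom_len - l, 1L) - 1L,
                  integer(1))
  gene_models(sprintf("g%03d", seq_len(n)),
              sample(chroms, n, replace = TRUE),
              sample(c("+", "-"), n, replace = TRUE),
              start, start + len)
}

# all-pairs half-open overlap check
brute_intersect <- function(rep1, rep2, min_overlap = 1L) {
  keep <- logical(nrow(rep1))
  for (i in seq_len(nrow(rep1))) {
    for (j in seq_len(nrow(rep2))) {
      if (rep1$chrom[i] != rep2$chrom[j]) next
      ov <- min(rep1$end[i], rep2$end[j]) - max(rep1$start[i], rep2$start[j])
      if (ov >= min_overlap) { keep[i] <- TRUE; break }
    }
  }
  rep1$name[keep]
}

# per-gene window scan with the stated precedence
brute_classify <- function(anchor, chrom, genes, pw = 10000L, dw = 10000L) {
  found <- c(promoter = FALSE, exon = FALSE, intron = FALSE,
             downstream = FALSE)
  for (j in seq_len(nrow(genes))) {
    if (genes$chrom[j] != chrom) next
    g <- genes[j, ]
    up <- if (g$strand == "+") g$tss - anchor else anchor - g$tss
    if (up >= 1 && up <= pw) found["promoter"] <- TRUE
    if (anchor >= g$tx_start && anchor < g$tx_end) {
      ex <- genes$exons[[j]]
      hit <- FALSE
      for (k in seq_len(nrow(ex))) {
        if (anchor >= ex[k, 1] && anchor < ex[k, 2]) hit <- TRUE
      }
      if (hit) found["exon"] <- TRUE else found["intron"] <- TRUE
    }
    dn <- if (g$strand == "+") anchor - g$tts else g$tts - anchor
    if (dn >= 1 && dn <= dw) found["downstream"] <- TRUE
  }
  for (cat in names(found)) if (found[cat]) return(cat)
  "intergenic"
}

brute_nearest <- function(anchor, chrom, genes) {
  best <- NULL
  for (j in order(genes$gene_id)) {
    if (genes$chrom[j] != chrom) next
    d <- abs(anchor - genes$tss[j])
    if (is.null(best) || d < best$d) {
      s <- if (genes$strand[j] == "+") 1L else -1L
      best <- list(gene = genes$gene_id[j], d = d,
                   signed = (anchor - genes$tss[j]) * s)
    }
  }
  best
}

# step-by-step running-sum walk (second, independent ES implementation)
walk_es <- function(sorted_stats, member, weight_p) {
  n <- length(sorted_stats)
  nh <- sum(member)
  nr <- sum(abs(sorted_stats[member])^weight_p)
  run <- 0
  best <- 0
  for (i in seq_len(n)) {
    if (member[i]) {
      run <- run + (if (nr > 0) abs(sorted_stats[i])^weight_p / nr
                    else 1 / nh)
    } else {
      run <- run - 1 / (n - nh)
    }
    if (abs(run) > abs(best)) best <- run
  }
  best
}

# exhaustive 4^w enumeration of the PWM score distribution
enum_pwm <- function(pwm) {
  w <- pwm$width
  grid <- as.matrix(expand.grid(rep(list(1:4), w)))
  scores <- numeric(nrow(grid))
  probs <- numeric(nrow(grid))
  for (r in seq_len(nrow(grid))) {
    scores[r] <- sum(pwm$log_odds[cbind(grid[r, ], seq_len(w))])
    probs[r] <- prod(pwm$background[grid[r, ]])
  }
  list(score = scores, prob = probs)
}

enum_pvalue <- function(enum, s) {
  # same equality contract as the DP: scores within 1e-7 bits are equal
  vapply(s, function(x) sum(enum$prob[enum$score >= x - 1e-7]), numeric(1))
}

revcomp_chr <- function(seq) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(seq, "")[[1]]), collapse = ""))
}

rand_pfm <- function(w) {
  m <- matrix(sample(0:60, 4 * w, replace = TRUE), nrow = 4,
              dimnames = list(c("A", "C", "G", "T"), NULL))
  bad <- colSums(m) == 0
  m[1, bad] <- 1
  m
}

rand_seq <- function(len, prob = rep(0.25, 4)) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE, prob = prob),
        collapse = "")
}
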
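#' Simulation configuration
#'
#' Defines the study conditions for the synthetic-data generator: a
#' miniature genome with stranded multi-exon genes, transcription-factor
#' peaks planted in five regulatory classes with class-conditional
#' bimodal histone-mark flanks and ATAC openness, motif-embedded peak
#' sequences, and a two-contrast knockdown differential-expression design
#' with planted direct targets.  Every artifact of a run is a pure
#' function of this configuration (one global seed feeding independent
#' sub-streams per component).
#'
#' @param seed global integer seed.
#' @param n_chroms,chrom_length genome size (default 2 x 500 kb).
#' @param n_genes number of genes (default 60), placed without overlap.
#' @param n_peaks number of peaks shared by both replicates (default 400).
#' @param class_proportions named fractions over
#'   `other/cAE/cIE/cAP/cIP`, summing to 1; the default mirrors the
#'   empirical ordering of transcription-factor cistromes (most peaks
#'   unmarked, active enhancers dominating the classified fraction).
#' @param open_prob_by_class probability that a peak of each class
#'   receives an overlapping open-chromatin interval.
#' @param motif_rates named planting probabilities for the TRE and CRE
#'   consensus motifs.
#' @param gc_content background G+C fraction of the genome.
#' @param n_direct_targets genes given concordant knockdown effects and a
#'   classified peak at their TSS (default 20).
#' @param effect_mean,effect_sd log2 fold-change effect distribution of
#'   direct targets (default 1 +/- 0.1, i.e. a two-fold effect).
#' @param null_sd log2 fold-change spread of unaffected genes; also the
#'   standard error of the z-model generating p-values, so null p-values
#'   are exactly Uniform(0, 1).
#' @param flank_mark_offset distance from the peak anchor to the centre
#'   of each planted mark interval (bimodal flanks, default 600 bp).
#' @param mark_width width of planted mark intervals (default 300 bp).
#' @param mark_noise probability of dropping a planted mark or adding a
#'   spurious one (default 0, the zero-noise study condition).
#' @param decoy_frac fraction of replicate-specific decoy peaks added to
#'   each replicate (default 0.05).
#' @param jitter_bp maximal replicate-2 coordinate jitter; kept at or
#'   below 50 bp so every shared peak of width >= 51 bp still overlaps
#'   its replicate-1 twin by at least 1 bp.
#' @param peak_width width of simulated peaks (default 300 bp).
#' @param atac_width width of planted open-chromatin intervals.
#' @param contrasts names of the two knockdown contrasts.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1234L,
                       n_chroms = 2L, chrom_length = 500000L,
                       n_genes = 60L, n_peaks = 400L,
                       class_proportions = c(other = 0.60, cAE = 0.27,
                                             cIE = 0.09, cAP = 0.03,
                                             cIP = 0.01),
                       open_prob_by_class = c(cAE = 0.964, cAP = 0.928,
                                              cIE = 0.2, cIP = 0.2,
                                              other = 0.05),
                       motif_rates = c(TRE = 0.9, CRE = 0.2),
                       gc_content = 0.5,
                       n_direct_targets = 20L,
                       effect_mean = 1, effect_sd = 0.1, null_sd = 0.05,
                       flank_mark_offset = 600L, mark_width = 300L,
                       mark_noise = 0,
                       decoy_frac = 0.05, jitter_bp = 50L,
                       peak_width = 300L, atac_width = 500L,
                       contrasts = c("siTF_1", "siTF_2")) {
  stopifnot(abs(sum(class_proportions) - 1) < 1e-9,
            all(class_proportions >= 0),
            all(open_prob_by_class >= 0 & open_prob_by_class <= 1),
            all(motif_rates >= 0 & motif_rates <= 1),
            gc_content > 0, gc_content < 1,
            effect_mean > 0, effect_sd >= 0, null_sd > 0,
            mark_noise >= 0, mark_noise <= 1,
            jitter_bp >= 0, jitter_bp <= 50,
            peak_width > 2 * jitter_bp)
  if (chrom_length < 100 * n_genes / n_chroms) {
    stop("genome too small for the requested gene count")
  }
  structure(as.list(environment()), class = "sim_config")
}

# independent sub-streams derived from the global seed
.substream <- function(seed, k) {
  set.seed((as.integer(seed) + 99991L * k) %% 2147483629L)
}

.apportion <- function(n, props) {
  if (n == 0) {
    return(stats::setNames(integer(length(props)), names(props)))
  }
  base <- floor(n * props)
  rem <- n - sum(base)
  if (rem > 0) {
    frac <- n * props - base
    add <- order(-frac, seq_along(props))[seq_len(rem)]
    base[add] <- base[add] + 1
  }
  stats::setNames(as.integer(base), names(props))
}

#' Simulate a miniature genome with gene models
#'
#' Draws i.i.d. bases at the configured GC content and places
#' `n_genes` non-overlapping stranded genes with 2-8 exons each, evenly
#' apportioned across chromosomes in disjoint slots (so transcription
#' start sites are well separated).  Deterministic given the seed.
#'
#' @param config a [sim_config()].
#' @return A list: `genome` (`DNAStringSet` named chr1, chr2, ...) and
#'   `genes` (a [gene_models()] table).
#' @export
simulate_genome <- function(config) {
  .substream(config$seed, 1L)
  pbase <- c(A = (1 - config$gc_content) / 2, C = config$gc_content / 2,
             G = config$gc_content / 2, T = (1 - config$gc_content) / 2)
  chroms <- paste0("chr", seq_len(config$n_chroms))
  genome <- Biostrings::DNAStringSet(vapply(chroms, function(ch) {
    paste(sample(DNA, config$chrom_length, replace = TRUE, prob = pbase),
          collapse = "")
  }, character(1)))
  names(genome) <- chroms

  .substream(config$seed, 2L)
  per <- .apportion(config$n_genes,
                    rep(1 / config$n_chroms, config$n_chroms))
  gid <- 0L
  recs <- list()
  for (ci in seq_len(config$n_chroms)) {
    np <- per[ci]
    if (np == 0L) next
    slot_len <- (config$chrom_length - 4000L) %/% np
    if (slot_len < 3500L) {
      stop("gene placement infeasible: increase chrom_length or reduce ",
           "n_genes")
    }
    for (i in seq_len(np)) {
      gid <- gid + 1L
      slot_start <- 2000L + (i - 1L) * slot_len
      glen <- sample(2000L:min(8000L, slot_len - 1000L), 1L)
      tx_start <- slot_start + sample.int(slot_len - glen - 500L, 1L)
      tx_end <- tx_start + glen
      k <- sample(2:8, 1L)
      cuts <- sort(sample((tx_start + 1L):(tx_end - 1L), 2L * k - 2L))
      starts <- c(tx_start, cuts[seq(2, length(cuts), by = 2)])
      ends <- c(cuts[seq(1, length(cuts), by = 2)], tx_end)
      recs[[gid]] <- list(gene_id = sprintf("gene_%03d", gid),
                          chrom = paste0("chr", ci),
                          strand = sample(c("+", "-"), 1L),
                          tx_start = tx_start, tx_end = tx_end,
                          exons = cbind(start = starts, end = ends))
    }
  }
  genes <- gene_models(vapply(recs, `[[`, character(1), "gene_id"),
                       vapply(recs, `[[`, character(1), "chrom"),
                       vapply(recs, `[[`, character(1), "strand"),
                       vapply(recs, `[[`, integer(1), "tx_start"),
                       vapply(recs, `[[`, integer(1), "tx_end"),
                       lapply(recs, `[[`, "exons"))
  list(genome = genome, genes = genes)
}

# consensus strings planted by the generator; the shipped synthetic PFMs
# have these as their unique best-scoring word
.SIM_MOTIFS <- c(TRE = "TGAGTCA", CRE = "TGACGTCA")

#' Simulate peaks, marks, ATAC intervals and motif-embedded sequences
#'
#' Plants `n_peaks` shared peaks in disjoint slots at least 1.8 kb apart
#' (so one peak's mark flanks can never enter a neighbour's +/-1 kb
#' presence window), labels them by class, and places the class-defining
#' histone-mark intervals as bimodal flanks at
#' `+/- flank_mark_offset` of each anchor.  One classified peak is placed
#' within 1 kb of the TSS of each designated direct-target gene, whose
#' TSS is chosen to be at least 4 kb from any other TSS so the
#' nearest-TSS assignment of its peak is unambiguous.  Replicate 2 is a
#' jittered copy of replicate 1 plus replicate-specific decoy peaks;
#' motif consensus strings are embedded in place (base replacement, no
#' insertion) at the configured rates.
#'
#' @param config a [sim_config()].
#' @param genome,genes output of [simulate_genome()].
#' @return A list: `rep1`, `rep2` (peak sets), `marks` (named list of
#'   three mark [peak_set()]s), `atac`, `genome` (with motifs embedded)
#'   and `truth` (class labels, openness, planted motifs, direct-target
#'   table with directions and supporting peak names).
#' @export
simulate_cistrome <- function(config, genome, genes) {
  .substream(config$seed, 3L)
  pw <- config$peak_width
  half <- pw %/% 2L
  nt <- config$n_direct_targets

  # --- direct-target genes: isolated TSSs, one classified peak each
  iso <- vapply(seq_len(nrow(genes)), function(i) {
    same <- genes$chrom == genes$chrom[i]
    d <- abs(genes$tss[same] - genes$tss[i])
    min(d[d > 0], Inf)
  }, numeric(1))
  candidates <- which(iso >= 4000)
  if (length(candidates) < nt) {
    stop("not enough isolated genes for ", nt, " direct targets")
  }
  target_idx <- sort(sample(candidates, nt))
  target_dir <- sample(rep_len(c("up", "down"), nt))
  t_anchor <- genes$tss[target_idx] +
    sample(c(-1L, 1L), nt, replace = TRUE) *
    sample(200:1000, nt, replace = TRUE)
  t_chrom <- genes$chrom[target_idx]

  # --- class counts (largest remainder), target peaks take classified ones
  counts <- .apportion(config$n_peaks, config$class_proportions)
  cl_classes <- intersect(names(counts), c("cAP", "cAE", "cIP", "cIE"))
  cl_counts <- counts[cl_classes]
  if (sum(cl_counts) < nt) {
    stop("n_direct_targets exceeds the number of classified peaks")
  }
  t_alloc <- .apportion(nt, cl_counts / sum(cl_counts))
  t_class <- sample(rep(names(t_alloc), t_alloc))
  fill_counts <- counts
  fill_counts[names(t_alloc)] <- fill_counts[names(t_alloc)] - t_alloc
  n_fill <- sum(fill_counts)

  # --- filler and decoy peaks on a 1.85-kb slot lattice
  slot_by <- 1850L
  slots <- do.call(rbind, lapply(seq_len(config$n_chroms), function(ci) {
    pos <- seq(2500L, config$chrom_length - 2500L, by = slot_by)
    data.frame(chrom = paste0("chr", ci), pos = pos,
               stringsAsFactors = FALSE)
  }))
  near_target <- vapply(seq_len(nrow(slots)), function(i) {
    t <- t_anchor[t_chrom == slots$chrom[i]]
    length(t) > 0 && any(abs(t - slots$pos[i]) < 1900L)
  }, logical(1))
  avail <- which(!near_target)
  n_decoy <- round(config$n_peaks * config$decoy_frac)
  if (length(avail) < n_fill + 2L * n_decoy) {
    stop("peak placement infeasible: increase chrom_length or reduce ",
         "n_peaks")
  }
  picked <- sample(avail, n_fill + 2L * n_decoy)
  f_slot <- picked[seq_len(n_fill)]
  d1_slot <- picked[n_fill + seq_len(n_decoy)]
  d2_slot <- picked[n_fill + n_decoy + seq_len(n_decoy)]
  jit <- function(n) sample(-50:50, n, replace = TRUE)
  f_anchor <- slots$pos[f_slot] + jit(n_fill)
  f_chrom <- slots$chrom[f_slot]
  f_class <- sample(rep(names(fill_counts), fill_counts))

  anchor <- c(t_anchor, f_anchor)
  chrom <- c(t_chrom, f_chrom)
  class <- c(t_class, f_class)
  is_target <- c(rep(TRUE, nt), rep(FALSE, n_fill))
  target_gene <- c(genes$gene_id[target_idx], rep(NA_character_, n_fill))
  ord <- order(chrom, anchor)
  anchor <- anchor[ord]; chrom <- chrom[ord]; class <- class[ord]
  is_target <- is_target[ord]; target_gene <- target_gene[ord]
  nm <- sprintf("peak_%04d", seq_along(anchor))

  shared <- peak_set(chrom, anchor - half, anchor - half + pw, name = nm,
                     score = 100, summit_offset = half,
                     source_label = "rep1")

  # --- class-conditional histone-mark flanks (bimodal), with noise
  mark_of <- list(cAP = c("H3K27ac", "H3K4me3"),
                  cAE = c("H3K27ac", "H3K4me1"),
                  cIP = "H3K4me3", cIE = "H3K4me1", other = character(0))
  all_marks <- c("H3K27ac", "H3K4me1", "H3K4me3")
  mk <- list(H3K27ac = list(), H3K4me1 = list(), H3K4me3 = list())
  off <- config$flank_mark_offset
  mw <- config$mark_width
  for (i in seq_along(anchor)) {
    present <- mark_of[[class[i]]]
    if (config$mark_noise > 0) {
      drop <- stats::runif(length(present)) < config$mark_noise
      spurious <- setdiff(all_marks, present)
      add <- spurious[stats::runif(length(spurious)) < config$mark_noise]
      present <- c(present[!drop], add)
    }
    for (m in present) {
      mk[[m]][[length(mk[[m]]) + 1L]] <- data.frame(
        chrom = chrom[i],
        start = c(anchor[i] - off - mw %/% 2L, anchor[i] + off - mw %/% 2L),
        end = c(anchor[i] - off + mw %/% 2L, anchor[i] + off + mw %/% 2L))
    }
  }
  marks <- lapply(stats::setNames(names(mk), names(mk)), function(m) {
    if (length(mk[[m]]) == 0L) return(empty_peak_set(m))
    d <- do.call(rbind, mk[[m]])
    peak_set(d$chrom, d$start, d$end, source_label = m)
  })

  # --- open chromatin
  p_open <- config$open_prob_by_class[class]
  open <- stats::runif(length(anchor)) < p_open
  aw <- config$atac_width
  atac <- if (any(open)) {
    peak_set(chrom[open], anchor[open] - aw %/% 2L,
             anchor[open] + aw %/% 2L, source_label = "ATAC")
  } else empty_peak_set("ATAC")

  # --- replicate 2: jittered copy + decoys
  shift <- if (config$jitter_bp > 0) {
    sample(-config$jitter_bp:config$jitter_bp, length(anchor),
           replace = TRUE)
  } else rep(0L, length(anchor))
  rep2 <- peak_set(chrom, shared$start + shift, shared$end + shift,
                   name = paste0("r2_", nm), score = 100,
                   summit_offset = half, source_label = "rep2")
  decoy <- function(slot_idx, label) {
    if (length(slot_idx) == 0L) return(empty_peak_set(label))
    a <- slots$pos[slot_idx] + jit(length(slot_idx))
    peak_set(slots$chrom[slot_idx], a - half, a - half + pw,
             name = sprintf("%s_decoy_%03d", label, seq_along(slot_idx)),
             score = 50, summit_offset = half, source_label = label)
  }
  rep1 <- rbind(shared, decoy(d1_slot, "rep1"))
  rep2 <- rbind(rep2, decoy(d2_slot, "rep2"))
  class(rep1) <- class(rep2) <- c("peak_set", "data.frame")
  attr(rep1, "source_label") <- "rep1"
  attr(rep2, "source_label") <- "rep2"

  # --- motif embedding (base replacement at fixed offsets within peaks)
  .substream(config$seed, 4L)
  seqs <- as.character(genome)
  planted <- list()
  for (i in seq_along(anchor)) {
    for (m in names(config$motif_rates)) {
      if (stats::runif(1) >= config$motif_rates[[m]]) next
      word <- .SIM_MOTIFS[[m]]
      lo <- if (m == "TRE") 30L else 170L
      hi <- if (m == "TRE") 110L else pw - nchar(word) - 30L
      offm <- sample(lo:hi, 1L)
      s0 <- shared$start[i] + offm  # 0-based genome offset
      substr(seqs[[chrom[i]]], s0 + 1L, s0 + nchar(word)) <- word
      planted[[length(planted) + 1L]] <- data.frame(
        peak_name = nm[i], motif = m, offset = offm, strand = "+",
        stringsAsFactors = FALSE)
    }
  }
  genome2 <- Biostrings::DNAStringSet(seqs)
  names(genome2) <- names(genome)
  planted <- if (length(planted)) do.call(rbind, planted) else
    data.frame(peak_name = character(), motif = character(),
               offset = integer(), strand = character())

  truth <- list(
    peak_class = stats::setNames(class, nm),
    peak_open = stats::setNames(open, nm),
    planted_motifs = planted,
    direct_targets = data.frame(
      gene_id = target_gene[is_target],
      direction = target_dir[match(target_gene[is_target],
                                   genes$gene_id[target_idx])],
      peak_name = nm[is_target],
      stringsAsFactors = FALSE))
  list(rep1 = rep1, rep2 = rep2, marks = marks, atac = atac,
       genome = genome2, truth = truth)
}

#' Simulate two-contrast differential-expression tables
#'
#' Direct-target genes receive log2 fold changes drawn from
#' `Normal(+/- effect_mean, effect_sd)` with the same sign in both
#' contrasts; all other genes from `Normal(0, null_sd)`.  P-values come
#' from a one-sample z-model with standard error `null_sd`
#' (`p = 2 * pnorm(-|log2fc| / null_sd)`), so null p-values are exactly
#' uniform and a two-fold planted effect passes the 1.25-fold / FDR
#' filter with overwhelming probability.
#'
#' @param config a [sim_config()].
#' @param genes a [gene_models()] table.
#' @param truth truth list from [simulate_cistrome()] (its
#'   `direct_targets` table supplies genes and directions); pass `NULL`
#'   for a null-only table.
#' @return A `data.frame`: `gene_id`, `contrast`, `log2fc`, `pvalue`,
#'   with attribute `true_log2fc` (genes x contrasts matrix).
#' @export
simulate_de_tables <- function(config, genes, truth = NULL) {
  .substream(config$seed, 5L)
  targets <- if (is.null(truth)) {
    data.frame(gene_id = character(), direction = character())
  } else unique(truth$direct_targets[, c("gene_id", "direction")])
  out <- list()
  fc_mat <- matrix(0, nrow(genes), length(config$contrasts),
                   dimnames = list(genes$gene_id, config$contrasts))
  for (ct in config$contrasts) {
    lfc <- stats::rnorm(nrow(genes), 0, config$null_sd)
    hit <- match(targets$gene_id, genes$gene_id)
    if (length(hit)) {
      sgn <- ifelse(targets$direction == "up", 1, -1)
      lfc[hit] <- stats::rnorm(length(hit), sgn * config$effect_mean,
                               config$effect_sd)
    }
    p <- pmax(2 * stats::pnorm(-abs(lfc) / config$null_sd), 1e-300)
    fc_mat[, ct] <- lfc
    out[[ct]] <- data.frame(gene_id = genes$gene_id, contrast = ct,
                            log2fc = lfc, pvalue = p,
                            stringsAsFactors = FALSE)
  }
  de <- do.call(rbind, out)
  rownames(de) <- NULL
  attr(de, "true_log2fc") <- fc_mat
  de
}

#' Run the full generator and optionally write its files
#'
#' Produces genome, gene models, replicate peak sets, mark and ATAC
#' intervals, DE tables and the planted truth, and (when `out_dir` is
#' given) writes them in the standard formats: `genome.fa`, `genes.gtf`,
#' `rep1.narrowPeak`, `rep2.narrowPeak`, `H3K27ac.bed`, `H3K4me1.bed`,
#' `H3K4me3.bed`, `atac.bed`, `de.tsv` and `truth.json`.
#'
#' @param config a [sim_config()].
#' @param out_dir optional output directory (created if needed).
#' @return A list with all simulated objects and `truth`.
#' @export
simulate_study <- function(config = sim_config(), out_dir = NULL) {
  g <- simulate_genome(config)
  cis <- simulate_cistrome(config, g$genome, g$genes)
  de <- simulate_de_tables(config, g$genes, cis$truth)
  res <- list(config = config, genome = cis$genome, genes = g$genes,
              rep1 = cis$rep1, rep2 = cis$rep2, marks = cis$marks,
              atac = cis$atac, de = de, truth = cis$truth)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    Biostrings::writeXStringSet(res$genome, file.path(out_dir, "genome.fa"))
    write_gene_models(res$genes, file.path(out_dir, "genes.gtf"))
    write_peaks(res$rep1, file.path(out_dir, "rep1.narrowPeak"))
    write_peaks(res$rep2, file.path(out_dir, "rep2.narrowPeak"))
    for (m in names(res$marks)) {
      write_peaks(res$marks[[m]], file.path(out_dir, paste0(m, ".bed")),
                  format = "bed")
    }
    write_peaks(res$atac, file.path(out_dir, "atac.bed"), format = "bed")
    utils::write.table(res$de, file.path(out_dir, "de.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(list(
      peak_class = as.list(res$truth$peak_class),
      peak_open = as.list(res$truth$peak_open),
      planted_motifs = res$truth$planted_motifs,
      direct_targets = res$truth$direct_targets),
      file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  }
  res
}
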
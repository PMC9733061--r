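#' Gene models
#'
#' A gene model table is a `data.frame` with one row per gene: `gene_id`,
#' `chrom`, `strand` (`"+"`/`"-"`), `tx_start`/`tx_end` (0-based half-open
#' transcript span), `tss`/`tts` (strand-aware transcription start /
#' termination positions: for a `+` gene `tss = tx_start` and
#' `tts = tx_end - 1`, mirrored for `-`), and a list-column `exons` holding
#' per-gene two-column matrices of 0-based half-open exon coordinates,
#' sorted and non-overlapping.
#'
#' @param gene_id,chrom,strand,tx_start,tx_end per-gene vectors.
#' @param exons list of two-column matrices (start, end), 0-based half-open;
#'   one per gene.  Defaults to a single exon spanning the transcript.
#' @return A `data.frame` of class `gene_models`.
#' @export
gene_models <- function(gene_id, chrom, strand, tx_start, tx_end,
                        exons = NULL) {
  n <- length(gene_id)
  tx_start <- as.integer(tx_start)
  tx_end <- as.integer(tx_end)
  if (any(tx_start >= tx_end)) stop("tx_start must be < tx_end")
  if (!all(strand %in% c("+", "-"))) stop("gene strand must be '+' or '-'")
  if (anyDuplicated(gene_id)) stop("gene_id values must be unique")
  if (is.null(exons)) {
    exons <- lapply(seq_len(n), function(i) {
      cbind(start = tx_start[i], end = tx_end[i])
    })
  }
  exons <- lapply(seq_len(n), function(i) {
    ex <- exons[[i]]
    ex <- matrix(as.integer(ex), ncol = 2,
                 dimnames = list(NULL, c("start", "end")))
    ex <- ex[order(ex[, 1]), , drop = FALSE]
    if (any(ex[, 1] >= ex[, 2])) {
      stop("degenerate exon in gene ", gene_id[i])
    }
    if (any(ex[, 1] < tx_start[i]) || any(ex[, 2] > tx_end[i])) {
      stop("exon outside transcript span in gene ", gene_id[i])
    }
    if (nrow(ex) > 1 && any(ex[-1, 1] < ex[-nrow(ex), 2])) {
      stop("overlapping exons in gene ", gene_id[i])
    }
    ex
  })
  gm <- data.frame(gene_id = as.character(gene_id),
                   chrom = as.character(chrom),
                   strand = as.character(strand),
                   tx_start = tx_start, tx_end = tx_end,
                   stringsAsFactors = FALSE)
  gm$tss <- ifelse(gm$strand == "+", gm$tx_start, gm$tx_end - 1L)
  gm$tts <- ifelse(gm$strand == "+", gm$tx_end - 1L, gm$tx_start)
  gm$exons <- exons
  class(gm) <- c("gene_models", "data.frame")
  gm
}

#' Read gene models from a GTF file
#'
#' Parses a GTF (1-based inclusive; converted to the internal 0-based
#' half-open convention at this boundary) via `rtracklayer` and reduces it
#' to one transcript per gene.  When a gene has several transcripts the
#' longest one is kept, so downstream gene-level set logic never counts a
#' gene twice.
#'
#' @param path path to a GTF file with `gene_id`/`transcript_id` attributes.
#' @return A [gene_models()] table.
#' @export
read_gene_models <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  gr <- rtracklayer::import(path, format = "gtf")
  ex <- gr[tolower(as.character(gr$type)) == "exon"]
  if (length(ex) == 0L) stop("no exon records in '", path, "'")
  tx <- as.character(ex$transcript_id)
  gid <- as.character(ex$gene_id)
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(ex)),
                   start = GenomicRanges::start(ex) - 1L,  # to 0-based
                   end = GenomicRanges::end(ex),
                   strand = as.character(GenomicRanges::strand(ex)),
                   gene_id = gid, tx_id = tx,
                   stringsAsFactors = FALSE)
  # transcript spans; keep the longest transcript of each gene
  spans <- do.call(rbind, lapply(split(df, df$tx_id), function(d) {
    data.frame(tx_id = d$tx_id[1], gene_id = d$gene_id[1],
               chrom = d$chrom[1], strand = d$strand[1],
               tx_start = min(d$start), tx_end = max(d$end),
               stringsAsFactors = FALSE)
  }))
  spans$len <- spans$tx_end - spans$tx_start
  spans <- spans[order(spans$gene_id, -spans$len, spans$tx_id), ]
  spans <- spans[!duplicated(spans$gene_id), ]
  exons <- lapply(spans$tx_id, function(t) {
    d <- df[df$tx_id == t, , drop = FALSE]
    d <- d[order(d$start), ]
    cbind(start = d$start, end = d$end)
  })
  gene_models(spans$gene_id, spans$chrom, spans$strand,
              spans$tx_start, spans$tx_end, exons)
}

#' Read gene models from a BED12 file
#'
#' Alternative gene-model source: one BED12 line per transcript
#' (0-based half-open, block fields 11-12 give the exon structure).
#' The longest transcript per gene is kept; the BED name field is used as
#' the gene identifier.
#'
#' @param path path to a BED12 file.
#' @return A [gene_models()] table.
#' @export
read_gene_models_bed12 <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 12L)) {
    stop(sprintf("malformed BED12 line %d in '%s': %d field(s)",
                 lineno[which(nf < 12L)[1L]], path, min(nf)))
  }
  recs <- lapply(fields, function(f) {
    start <- as.integer(f[2])
    sizes <- as.integer(strsplit(sub(",$", "", f[11]), ",")[[1]])
    offs <- as.integer(strsplit(sub(",$", "", f[12]), ",")[[1]])
    list(gene_id = f[4], chrom = f[1], strand = f[6],
         tx_start = start, tx_end = as.integer(f[3]),
         exons = cbind(start = start + offs, end = start + offs + sizes))
  })
  len <- vapply(recs, function(r) r$tx_end - r$tx_start, integer(1))
  gid <- vapply(recs, `[[`, character(1), "gene_id")
  recs <- recs[order(gid, -len)]
  recs <- recs[!duplicated(vapply(recs, `[[`, character(1), "gene_id"))]
  gene_models(vapply(recs, `[[`, character(1), "gene_id"),
              vapply(recs, `[[`, character(1), "chrom"),
              vapply(recs, `[[`, character(1), "strand"),
              vapply(recs, `[[`, integer(1), "tx_start"),
              vapply(recs, `[[`, integer(1), "tx_end"),
              lapply(recs, `[[`, "exons"))
}

#' Write gene models to a GTF file
#'
#' Emits one transcript per gene with `transcript` and `exon` features
#' (converting back to GTF's 1-based inclusive coordinates), suitable for
#' re-reading with [read_gene_models()].
#'
#' @param genes a [gene_models()] table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(genes, path) {
  lines <- character(0)
  for (i in seq_len(nrow(genes))) {
    attrs <- sprintf('gene_id "%s"; transcript_id "%s.t1";',
                     genes$gene_id[i], genes$gene_id[i])
    lines <- c(lines, paste(genes$chrom[i], "cistargets", "transcript",
                            genes$tx_start[i] + 1L, genes$tx_end[i],
                            ".", genes$strand[i], ".", attrs, sep = "\t"))
    ex <- genes$exons[[i]]
    for (j in seq_len(nrow(ex))) {
      lines <- c(lines, paste(genes$chrom[i], "cistargets", "exon",
                              ex[j, 1] + 1L, ex[j, 2],
                              ".", genes$strand[i], ".", attrs, sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
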
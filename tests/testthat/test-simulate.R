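small_cfg <- function(...) {
  args <- utils::modifyList(
    list(seed = 555, n_chroms = 1L, chrom_length = 200000L,
         n_genes = 10L, n_peaks = 60L, n_direct_targets = 5L),
    list(...))
  do.call(sim_config, args)
}

test_that("the generator is deterministic given its seed", {
  a <- simulate_study(small_cfg())
  b <- simulate_study(small_cfg())
  expect_identical(as.character(a$genome), as.character(b$genome))
  expect_identical(a$rep1, b$rep1)
  expect_identical(a$de, b$de)
  expect_identical(a$truth, b$truth)
  c <- simulate_study(small_cfg(seed = 556))
  expect_false(identical(as.character(a$genome), as.character(c$genome)))
})

test_that("genome composition and gene counts follow the configuration", {
  sim <- simulate_genome(small_cfg(gc_content = 0.4))
  expect_equal(nrow(sim$genes), 10L)
  expect_equal(length(sim$genome), 1L)
  gc <- sum(Biostrings::letterFrequency(sim$genome, c("G", "C"))) /
    sum(Biostrings::width(sim$genome))
  se <- sqrt(0.4 * 0.6 / sum(Biostrings::width(sim$genome)))
  expect_lt(abs(gc - 0.4), 3 * se)
  # genes are non-overlapping with 2-8 sorted exons inside the span
  g <- sim$genes[order(sim$genes$tx_start), ]
  expect_true(all(g$tx_start[-1] >= g$tx_end[-nrow(g)]))
  for (ex in g$exons) {
    expect_true(nrow(ex) >= 2 && nrow(ex) <= 8)
    expect_true(all(diff(ex[, 1]) > 0))
  }
})

test_that("zero-noise runs reproduce every planted label end to end", {
  sim <- simulate_study(small_cfg())
  common <- intersect_replicates(sim$rep1, sim$rep2)
  expect_equal(sort(common$name), sort(names(sim$truth$peak_class)))
  cls <- classify_chromatin_states(common, sim$marks$H3K27ac,
                                   sim$marks$H3K4me1, sim$marks$H3K4me3,
                                   sim$atac)
  expect_equal(cls$state,
               unname(sim$truth$peak_class[cls$peak_name]))
  expect_equal(cls$open_chromatin,
               unname(sim$truth$peak_open[cls$peak_name]))
})

test_that("degenerate class mixes behave as planted", {
  cfg <- small_cfg(class_proportions = c(other = 1, cAE = 0, cIE = 0,
                                         cAP = 0, cIP = 0),
                   n_direct_targets = 0L)
  sim <- simulate_study(cfg)
  expect_equal(sum(vapply(sim$marks, nrow, integer(1))), 0L)
  cfg2 <- small_cfg(motif_rates = c(TRE = 1, CRE = 0))
  sim2 <- simulate_study(cfg2)
  common <- intersect_replicates(sim2$rep1, sim2$rep2)
  res <- peak_motif_fractions(common, sim2$genome,
                              cistargets_pfms()["TRE"], 1e-4)
  expect_equal(res$summary$fraction, 1)
})

test_that("planted motifs sit at their recorded offsets", {
  sim <- simulate_study(small_cfg())
  seqs <- peak_sequences(sim$rep1, sim$genome)
  pm <- sim$truth$planted_motifs
  words <- c(TRE = "TGAGTCA", CRE = "TGACGTCA")
  for (i in seq_len(nrow(pm))) {
    w <- words[[pm$motif[i]]]
    expect_equal(substr(seqs[[pm$peak_name[i]]], pm$offset[i] + 1,
                        pm$offset[i] + nchar(w)), w)
  }
})

test_that("written fixtures re-read through the package readers reproduce the truth", {
  dir <- withr::local_tempdir()
  sim <- simulate_study(small_cfg(), out_dir = dir)
  expect_true(all(file.exists(file.path(dir, c(
    "genome.fa", "genes.gtf", "rep1.narrowPeak", "rep2.narrowPeak",
    "H3K27ac.bed", "H3K4me1.bed", "H3K4me3.bed", "atac.bed", "de.tsv",
    "truth.json")))))
  rep1 <- read_peaks(file.path(dir, "rep1.narrowPeak"))
  rep2 <- read_peaks(file.path(dir, "rep2.narrowPeak"))
  genes <- read_gene_models(file.path(dir, "genes.gtf"))
  marks <- lapply(c(H3K27ac = "H3K27ac", H3K4me1 = "H3K4me1",
                    H3K4me3 = "H3K4me3"), function(m) {
    read_peaks(file.path(dir, paste0(m, ".bed")))
  })
  atac <- read_peaks(file.path(dir, "atac.bed"))
  de <- read_de_table(file.path(dir, "de.tsv"))
  expect_equal(rep1$start, sim$rep1$start)
  expect_equal(genes$tx_start, sim$genes$tx_start[order(sim$genes$gene_id)])
  expect_equal(genes$exons, sim$genes$exons[order(sim$genes$gene_id)])
  res <- run_pipeline(rep1, rep2, genes, marks, atac, de,
                      genome = file.path(dir, "genome.fa"))
  tt <- sim$truth$direct_targets
  expect_setequal(res$targets$nominations$gene_id, unique(tt$gene_id))
  m <- merge(res$targets$nominations, unique(tt[, c("gene_id", "direction")]),
             by = "gene_id")
  expect_true(all(m$direction.x == m$direction.y))
  expect_equal(res$classifications$state,
               unname(sim$truth$peak_class[res$classifications$peak_name]))
})

test_that("planted-target recovery degrades monotonically with mark noise", {
  rec <- vapply(c(0, 0.3, 0.8), function(noise) {
    sim <- simulate_study(small_cfg(mark_noise = noise))
    common <- intersect_replicates(sim$rep1, sim$rep2)
    cls <- classify_chromatin_states(common, sim$marks$H3K27ac,
                                     sim$marks$H3K4me1, sim$marks$H3K4me3,
                                     sim$atac)
    mean(cls$state == sim$truth$peak_class[cls$peak_name])
  }, numeric(1))
  expect_true(all(diff(rec) <= 0.05))  # non-increasing up to sampling slack
  expect_equal(rec[1], 1)
})

test_that("null-only DE tables produce no concordant calls at zero effect", {
  cfg <- small_cfg(n_direct_targets = 0L)
  sim <- simulate_genome(cfg)
  de <- simulate_de_tables(cfg, sim$genes, truth = NULL)
  sets <- filter_de(de)
  hc <- concordant_genes(sets[[1]], sets[[2]])
  expect_equal(length(hc$high_confidence), 0L)
})
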
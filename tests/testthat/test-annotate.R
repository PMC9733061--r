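gene_plus <- gene_models("gA", "chr1", "+", 50000, 60000)

test_that("the 10-kb promoter window boundary is inclusive upstream", {
  pk <- function(a) peak_set("chr1", a - 10, a + 10, name = "p")
  expect_equal(annotate_peaks(pk(41000), gene_plus)$category, "promoter")
  expect_equal(annotate_peaks(pk(40000), gene_plus)$category, "promoter")
  expect_equal(annotate_peaks(pk(39999), gene_plus)$category, "intergenic")
  # inside the gene body (single exon) and downstream window
  expect_equal(annotate_peaks(pk(55000), gene_plus)$category, "exon")
  expect_equal(annotate_peaks(pk(60500), gene_plus)$category, "downstream")
  expect_equal(annotate_peaks(pk(70001), gene_plus)$category, "intergenic")
})

test_that("signed nearest-TSS distances follow the gene orientation", {
  gm <- gene_models("gM", "chr1", "-", 10000, 20000)  # tss = 19999
  p <- peak_set("chr1", 20989, 21009)                 # anchor 20999
  nt <- nearest_tss(p, gm)
  expect_equal(nt$signed_tss_distance, -1000L)        # upstream of '-' gene
  p0 <- peak_set("chr1", 19989, 20010, summit_offset = 10)  # anchor at tss
  expect_equal(nearest_tss(p0, gm)$signed_tss_distance, 0L)
  # mirroring the strand flips the sign
  gm2 <- gene_models("gM", "chr1", "+", 10000, 20000)
  gm2$tss <- gm$tss  # same TSS position, opposite orientation
  expect_equal(nearest_tss(p, gm2)$signed_tss_distance, 1000L)
})

test_that("absolute-distance ties break to the smaller gene id and flag", {
  gm <- gene_models(c("gB", "gA"), "chr1", c("+", "+"),
                    c(1000, 3000), c(2000, 4000))  # tss 1000 and 3000
  p <- peak_set("chr1", 1990, 2010)                # anchor 2000, both 1000
  nt <- nearest_tss(p, gm)
  expect_equal(nt$gene_id, "gA")
  expect_true(nt$tie)
})

test_that("annotation agrees with the brute-force oracle", {
  set.seed(99)
  for (r in 1:10) {
    genes <- rand_genes(10, chrom_len = 200000L)
    peaks <- rand_peaks(100, chrom_len = 200000L)
    ann <- annotate_peaks(peaks, genes)
    for (i in seq_len(nrow(peaks))) {
      expect_identical(ann$category[i],
                       brute_classify(peaks$anchor[i], peaks$chrom[i],
                                      genes))
      nb <- brute_nearest(peaks$anchor[i], peaks$chrom[i], genes)
      expect_identical(ann$gene_id[i], nb$gene)
      expect_equal(abs(ann$signed_tss_distance[i]), nb$d)
    }
  }
})

test_that("nearest-TSS distances are translation invariant", {
  set.seed(3)
  genes <- rand_genes(8)
  peaks <- rand_peaks(40, chrom_len = 200000L)
  d0 <- nearest_tss(peaks, genes)$signed_tss_distance
  shift <- 12345L
  g2 <- gene_models(genes$gene_id, genes$chrom, genes$strand,
                    genes$tx_start + shift, genes$tx_end + shift)
  p2 <- peak_set(peaks$chrom, peaks$start + shift, peaks$end + shift,
                 name = peaks$name)
  expect_equal(nearest_tss(p2, g2)$signed_tss_distance, d0)
})

test_that("distance histogram uses a closed 'within' boundary", {
  ann <- data.frame(signed_tss_distance = c(0L, 49999L, 50000L, 120000L))
  h <- distance_distribution(ann, breaks = 50000L)
  expect_equal(h$count, c(3L, 1L))
  expect_equal(h$fraction, c(0.75, 0.25))
  expect_equal(h$cum_fraction[1], 0.75)
  expect_equal(fraction_within_tss(ann), 0.75)
  # unassigned peaks are excluded but reported
  ann2 <- rbind(ann, data.frame(signed_tss_distance = NA_integer_))
  h2 <- distance_distribution(ann2, breaks = 50000L)
  expect_equal(sum(h2$count), 4L)
  expect_equal(attr(h2, "n_unassigned"), 1L)
  expect_error(distance_distribution(ann, breaks = c(10, 10)), "increasing")
})

test_that("distance histogram matches a direct tally on simulated data", {
  set.seed(5)
  d <- as.integer(round(abs(c(rnorm(700, 0, 20000), runif(300, 0, 3e5)))))
  ann <- data.frame(signed_tss_distance = d * sample(c(-1L, 1L), 1000,
                                                     replace = TRUE))
  breaks <- c(10000L, 50000L, 100000L)
  h <- distance_distribution(ann, breaks)
  expect_equal(h$count,
               c(sum(d <= 10000), sum(d > 10000 & d <= 50000),
                 sum(d > 50000 & d <= 100000), sum(d > 100000)))
  expect_equal(sum(h$fraction), 1)
})

test_that("feature fractions partition the peak set", {
  ann <- data.frame(category = c("promoter", rep("intron", 4),
                                 rep("intergenic", 5)))
  fd <- feature_distribution(ann)
  expect_equal(fd$fraction[fd$category == "promoter"], 0.1)
  expect_equal(fd$fraction[fd$category == "intron"], 0.4)
  expect_equal(fd$fraction[fd$category == "intergenic"], 0.5)
  expect_equal(sum(fd$count), nrow(ann))
  expect_equal(sum(fd$fraction), 1)
})

test_that("peaks on chromosomes without genes fall back to intergenic", {
  p <- peak_set(c("chr1", "chrUn"), c(55000, 100), c(55100, 200))
  expect_warning(ann <- annotate_peaks(p, gene_plus), "absent")
  expect_equal(ann$category[2], "intergenic")
  expect_true(is.na(ann$gene_id[2]))
})
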
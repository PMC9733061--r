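test_that("mark midpoints land in the half-open bin right of the anchor", {
  p <- peak_set("chr1", 9850, 10150, summit_offset = 150)  # anchor 10000
  m <- peak_set("chr1", 9990, 10010)                       # midpoint 10000
  mat <- bin_signal(p, m)
  expect_equal(dim(mat), c(1L, 60L))
  expect_equal(which(mat[1, ] > 0), 31L)  # first bin right of center
  expect_equal(sum(mat), 1L)
  # no marks on the chromosome -> all-zero row
  expect_true(all(bin_signal(p, peak_set("chr2", 1, 10)) == 0))
  expect_error(bin_signal(p, m, n_bins = 59), "even")
})

test_that("bimodal flanking reads give a bimodal column profile equal to a direct histogram", {
  set.seed(21)
  anchors <- seq(20000L, 92000L, by = 8000L)  # windows stay disjoint
  p <- peak_set("chr1", anchors - 150L, anchors + 150L, summit_offset = 150L)
  offs <- as.integer(round(rnorm(500 * nrow(p), 0, 120))) +
    sample(c(-650L, 650L), 500 * nrow(p), replace = TRUE)
  mid <- rep(anchors, each = 500) + offs
  m <- peak_set("chr1", mid - 10L, mid + 10L)
  mat <- bin_signal(p, m)
  prof <- colSums(mat)
  # independent tally of the same draws: every midpoint vs every window
  ref <- integer(60)
  for (i in seq_len(nrow(p))) {
    rel <- mid - (anchors[i] - 3000L)
    inwin <- rel >= 0 & rel < 6000
    ref <- ref + tabulate(rel[inwin] %/% 100L + 1L, 60L)
  }
  expect_equal(unname(prof), ref)
  # modes sit in the bins containing -650 and +650
  expect_equal(which.max(prof[1:30]), 24L)   # bin [-700,-600)
  expect_equal(which.max(prof[31:60]) + 30L, 37L)  # bin [+600,+700)
})

test_that("mark presence uses a half-open +/- flank window", {
  p <- peak_set("chr1", 49850, 50150, summit_offset = 150)  # anchor 50000
  expect_true(mark_presence(p, peak_set("chr1", 50999, 51500)))
  expect_false(mark_presence(p, peak_set("chr1", 51000, 51500)))
  expect_true(mark_presence(p, peak_set("chr1", 48500, 49001)))
  expect_false(mark_presence(p, peak_set("chr1", 48500, 49000)))
})

test_that("mark presence matches the brute-force overlap oracle", {
  set.seed(31)
  p <- rand_peaks(300, chrom_len = 500000L)
  m <- rand_peaks(300, chrom_len = 500000L)
  got <- mark_presence(p, m, flank = 1000L)
  win <- peak_set(p$chrom, pmax(p$anchor - 1000L, 0L), p$anchor + 1000L,
                  name = p$name)
  expect_identical(got, win$name %in% brute_intersect(win, m))
})

test_that("the state rule table is total, exclusive and promoter-dominant", {
  cube <- expand.grid(ac = c(TRUE, FALSE), me1 = c(TRUE, FALSE),
                      me3 = c(TRUE, FALSE))
  states <- classify_regulatory_state(cube$ac, cube$me1, cube$me3)
  expect_equal(length(states), 8L)
  expect_true(all(states %in% c("cAP", "cAE", "cIP", "cIE", "other")))
  lookup <- function(ac, me1, me3) {
    states[cube$ac == ac & cube$me1 == me1 & cube$me3 == me3]
  }
  expect_equal(lookup(TRUE, TRUE, FALSE), "cAE")
  expect_equal(lookup(FALSE, FALSE, TRUE), "cIP")
  expect_equal(lookup(FALSE, TRUE, TRUE), "cIP")
  expect_equal(lookup(TRUE, TRUE, TRUE), "cAP")   # promoter mark dominates
  expect_equal(lookup(TRUE, FALSE, TRUE), "cAP")
  expect_equal(lookup(FALSE, TRUE, FALSE), "cIE")
  expect_equal(lookup(TRUE, FALSE, FALSE), "other")
  expect_equal(lookup(FALSE, FALSE, FALSE), "other")
})

test_that("swapping the methyl marks exchanges enhancer and promoter states", {
  # holds on the six cells where me1 and me3 do not co-occur; the two
  # co-occurrence cells are fixed points of the promoter-dominance rule
  cube <- expand.grid(ac = c(TRUE, FALSE), me1 = c(TRUE, FALSE),
                      me3 = c(TRUE, FALSE))
  plain <- classify_regulatory_state(cube$ac, cube$me1, cube$me3)
  swapped <- classify_regulatory_state(cube$ac, cube$me3, cube$me1)
  map <- c(cAP = "cAE", cAE = "cAP", cIP = "cIE", cIE = "cIP",
           other = "other")
  free <- !(cube$me1 & cube$me3)
  expect_identical(swapped[free], unname(map[plain[free]]))
  expect_identical(swapped[!free], plain[!free])
})

test_that("open chromatin uses full-interval overlap", {
  p <- peak_set("chr1", 100, 200)
  expect_true(open_chromatin_flag(p, peak_set("chr1", 150, 160)))
  expect_false(open_chromatin_flag(p, peak_set("chr1", 300, 400)))
  expect_false(open_chromatin_flag(p, peak_set("chr2", 100, 200)))
})

test_that("state summary fractions partition and openness stays in [0,1]", {
  cls <- data.frame(peak_name = sprintf("p%d", 1:10),
                    state = c(rep("cAE", 3), "cAP", rep("other", 6)),
                    open_chromatin = c(rep(TRUE, 4), rep(FALSE, 6)))
  s <- state_summary(cls)
  expect_equal(s$fraction[s$state == "cAE"], 0.3)
  expect_equal(s$fraction[s$state == "cAP"], 0.1)
  expect_equal(s$fraction[s$state == "other"], 0.6)
  expect_equal(sum(s$count), 10L)
  expect_equal(sum(s$fraction), 1)
  expect_true(all(s$open_fraction >= 0 & s$open_fraction <= 1, na.rm = TRUE))
})
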
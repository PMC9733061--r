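uniform_bg <- rep(0.25, 4)

test_that("log-odds construction matches hand arithmetic", {
  pfm <- matrix(c(0, 0, 0, 100), nrow = 4,
                dimnames = list(c("A", "C", "G", "T"), NULL))
  pwm <- build_pwm(pfm, pseudocount = 0.25, background = uniform_bg)
  # T cell: ((100 + 0.25*0.25) / (100 + 0.25)) / 0.25, in bits
  expect_equal(unname(pwm$log_odds["T", 1]),
               log2((100.0625 / 100.25) / 0.25), tolerance = 1e-12)
  expect_true(all(is.finite(pwm$log_odds)))
  # uniform column scores zero against a uniform background
  flat <- build_pwm(matrix(25, 4, 1), background = uniform_bg)
  expect_equal(unname(flat$log_odds[, 1]), rep(0, 4))
  expect_error(build_pwm(matrix(0, 4, 1)), "zero")
  expect_error(build_pwm(matrix(1, 4, 1), background = c(0, .5, .25, .25)),
               "positive")
})

test_that("bundled TRE and CRE matrices give their consensus anchors", {
  pfms <- cistargets_pfms()
  expect_equal(pwm_consensus(build_pwm(pfms$TRE)), "TGASTCA")
  expect_equal(pwm_consensus(build_pwm(pfms$CRE)), "TGACGTCA")
})

test_that("JASPAR-style PFM files parse with and without row labels", {
  f <- withr::local_tempfile(fileext = ".pfm")
  writeLines(c(">M1 test", "A [ 1 2 ]", "C [ 3 4 ]", "G [ 5 6 ]",
               "T [ 7 8 ]"), f)
  m <- read_pfm(f)
  expect_equal(m$M1["T", ], c(7, 8))
  writeLines(c("1 2", "3 4", "5 6", "7 8"), f)
  expect_equal(unname(read_pfm(f)[[1]]["G", ]), c(5, 6))
  writeLines(c(">M2", "A [ 1 ]", "C [ 2 ]"), f)
  expect_error(read_pfm(f), "expected 4")
})

test_that("exact p-values match the closed single-column form and are monotone", {
  pfm <- matrix(c(0, 0, 0, 100), 4)
  pwm <- build_pwm(pfm, background = uniform_bg)
  d <- score_distribution(pwm)
  expect_equal(exact_score_pvalue(pwm, max(d$score), d), 0.25)
  expect_equal(exact_score_pvalue(pwm, min(d$score), d), 1)
  expect_equal(exact_score_pvalue(pwm, -1e6, d), 1)  # total probability
  s <- seq(min(d$score) - 1, max(d$score) + 1, length.out = 50)
  p <- exact_score_pvalue(pwm, s, d)
  expect_true(all(diff(p) <= 1e-12))
})

test_that("DP p-values equal exhaustive enumeration for widths up to 6", {
  set.seed(61)
  for (w in 2:6) {
    for (rep in 1:2) {
      bg <- as.numeric(stats::rgamma(4, 5) + 1)
      bg <- bg / sum(bg)
      pwm <- build_pwm(rand_pfm(w), background = bg)
      en <- enum_pwm(pwm)
      d <- score_distribution(pwm)
      probes <- c(sort(unique(en$score)),
                  sort(unique(en$score)) - 1e-4, max(en$score) + 1)
      expect_equal(exact_score_pvalue(pwm, probes, d),
                   enum_pvalue(en, probes), tolerance = 1e-6)
    }
  }
})

test_that("consensus sequences match themselves on both strands", {
  # symmetric 50/50 degenerate position: TGACTCA is the reverse
  # complement of TGAGTCA and scores identically
  pfm <- matrix(2, 4, 7, dimnames = list(c("A", "C", "G", "T"), NULL))
  hot <- c(4, 3, 1, NA, 4, 2, 1)
  for (j in c(1:3, 5:7)) pfm[hot[j], j] <- 94
  pfm[c(2, 3), 4] <- 47
  pwm <- build_pwm(pfm, background = uniform_bg)
  hits <- scan_sequence("TGAGTCA", pwm, threshold_p = 2e-4)
  expect_equal(nrow(hits), 2L)
  expect_equal(hits$offset, c(0L, 0L))
  expect_setequal(hits$strand, c("+", "-"))
  expect_equal(hits$score[1], hits$score[2])
  # uninformative sequence yields nothing
  expect_equal(nrow(scan_sequence(strrep("A", 50), pwm, 1e-4)), 0L)
  # sequences shorter than the motif yield an empty hit table
  expect_equal(nrow(scan_sequence("TGA", pwm, 1e-4)), 0L)
})

test_that("scanning agrees with exhaustive window enumeration", {
  set.seed(71)
  for (rep in 1:3) {
    w <- sample(4:8, 1)
    pwm <- build_pwm(rand_pfm(w), background = uniform_bg)
    seq <- rand_seq(1000)
    thr <- 10^sample(c(-2, -3), 1)
    hits <- scan_sequence(seq, pwm, thr)
    en <- enum_pwm(pwm)
    # brute force: score every window on both strands, keep p <= thr
    ref <- list()
    for (o in 0:(nchar(seq) - w)) {
      win <- substr(seq, o + 1, o + w)
      for (str in c("+", "-")) {
        s <- if (str == "+") win else revcomp_chr(win)
        sc <- sum(pwm$log_odds[cbind(match(strsplit(s, "")[[1]],
                                           c("A", "C", "G", "T")),
                                     1:w)])
        pv <- enum_pvalue(en, sc)
        if (pv <= thr) {
          ref[[length(ref) + 1]] <- data.frame(offset = o, strand = str,
                                               score = sc, pvalue = pv)
        }
      }
    }
    ref <- if (length(ref)) do.call(rbind, ref) else
      data.frame(offset = integer(), strand = character(),
                 score = numeric(), pvalue = numeric())
    ref <- ref[order(ref$offset, ref$strand), ]
    expect_equal(hits$offset, ref$offset)
    expect_equal(hits$strand, ref$strand)
    expect_equal(hits$score, ref$score, tolerance = 1e-9)
    expect_equal(hits$pvalue, ref$pvalue, tolerance = 1e-9)
  }
})

test_that("windows containing N are skipped", {
  pwm <- build_pwm(cistargets_pfms()$TRE, background = uniform_bg)
  hits <- scan_sequence("TGANTCA", pwm, threshold_p = 0.99)
  expect_equal(nrow(hits), 0L)
})

test_that("scanning a sequence and its reverse complement mirror exactly", {
  set.seed(81)
  pwm <- build_pwm(rand_pfm(6), background = uniform_bg)
  d <- score_distribution(pwm)
  for (rep in 1:10) {
    seq <- rand_seq(300)
    fwd <- scan_sequence(seq, pwm, 0.01, d)
    rev <- scan_sequence(revcomp_chr(seq), pwm, 0.01, d)
    mirrored <- data.frame(offset = nchar(seq) - 6 - fwd$offset,
                           strand = ifelse(fwd$strand == "+", "-", "+"),
                           score = fwd$score, pvalue = fwd$pvalue)
    mirrored <- mirrored[order(mirrored$offset, mirrored$strand), ]
    rownames(mirrored) <- NULL
    expect_equal(rev, mirrored, tolerance = 1e-12)
  }
})

test_that("planted consensus motifs are recovered as peak fractions", {
  set.seed(91)
  # 10 peaks on a toy chromosome, TRE consensus embedded in 9
  L <- 20000L
  seqchar <- rand_seq(L)
  anchors <- seq(1000L, 19000L, by = 2000L)
  for (i in 1:9) {
    s0 <- anchors[i] - 3L
    substr(seqchar, s0 + 1L, s0 + 7L) <- "TGAGTCA"
  }
  genome <- Biostrings::DNAStringSet(c(chrA = seqchar))
  peaks <- peak_set("chrA", anchors - 150L, anchors + 150L)
  res <- peak_motif_fractions(peaks, genome, cistargets_pfms()["TRE"],
                              threshold_p = 1e-4)
  expect_gte(res$summary$fraction, 0.9)
  # order invariance
  sh <- peaks[sample(nrow(peaks)), ]
  class(sh) <- class(peaks)
  res2 <- peak_motif_fractions(sh, genome, cistargets_pfms()["TRE"], 1e-4)
  expect_equal(res2$summary$fraction, res$summary$fraction)
  # no PWMs -> empty summary
  expect_equal(nrow(peak_motif_fractions(peaks, genome, list())$summary), 0L)
  # out-of-bounds peaks are named in the error
  bad <- peak_set("chrA", L - 10L, L + 50L, name = "oops")
  expect_error(peak_motif_fractions(bad, genome, cistargets_pfms()["TRE"]),
               "oops")
})
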
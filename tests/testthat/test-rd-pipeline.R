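# rd_pipeline: binning, GC statistics and correction, alignment parsing.

test_that("rebin sums constituent bins and conserves totals", {
  trk <- make_track(c(1, 2, 3, 4), bin_size = 100L)
  expect_equal(rebin(trk, 100)$values$chr1, c(1, 2, 3, 4))
  expect_equal(rebin(trk, 200)$values$chr1, c(3, 7))

  # partial tail: 5 bins at 300 -> 2 output bins, second sums 2
  trk5 <- make_track(c(1, 1, 1, 5, 7), bin_size = 100L)
  expect_equal(rebin(trk5, 300)$values$chr1, c(3, 12))

  expect_error(rebin(trk, 250), "multiple")
  expect_error(rebin(trk, 0), "multiple")

  # conservation property across random tracks and bin sizes
  set.seed(7)
  for (rep in 1:5) {
    n <- sample(50:200, 1)
    v <- rpois(n, 20)
    t0 <- make_track(v, bin_size = 100L)
    for (bs in c(200, 300, 700, 1100)) {
      expect_identical(sum(rebin(t0, bs)$values$chr1), as.numeric(sum(v)))
    }
  }
})

test_that("gc_per_bin pools counts, not percentages", {
  ga <- compute_content(c(c = paste0(
    strrep("G", 80), strrep("A", 20),     # bin 1: gc 80 / at 20
    strrep("C", 20), strrep("T", 80))))   # bin 2: gc 20 / at 80
  expect_equal(gc_per_bin(ga, 100)$values$c, c(80, 20))
  expect_equal(gc_per_bin(ga, 200)$values$c, 50)

  ga2 <- compute_content(c(c = paste0(strrep("N", 100), strrep("GGAT", 25))))
  gcb <- gc_per_bin(ga2, 100)$values$c
  expect_true(is.na(gcb[1]))
  expect_equal(gcb[2], 50)
})

test_that("parse_alignments bins reads by start position with q0 tracking", {
  asm <- synthetic_assembly(c(chr1 = 1000))

  # empty file
  p <- write_test_sam(data.frame(chrom = character(), pos = integer()),
                      c(chr1 = 1000))
  tr <- parse_alignments(p, asm)
  expect_equal(sum(tr$rd_100$values$chr1), 0)

  # start-position assignment: 101, 150, 199 all in bin 2 (101-200)
  p2 <- write_test_sam(data.frame(chrom = "chr1", pos = c(5L, 101L, 150L, 199L),
                                  mapq = c(0L, 60L, 60L, 60L)),
                       c(chr1 = 1000))
  tr2 <- parse_alignments(p2, asm)
  expect_equal(tr2$rd_100$values$chr1[1:2], c(1, 3))
  expect_equal(tr2$q0_100$values$chr1[1:2], c(1, 0))
  expect_equal(tr2$stats$used, 4L)
})

test_that("parse_alignments applies read filters and input checks", {
  asm <- synthetic_assembly(c(chr1 = 1000))
  # flags: 1024 duplicate, 256 secondary, 2048 supplementary, 4 unmapped
  p <- write_test_sam(data.frame(chrom = "chr1", pos = c(10L, 20L, 30L, 40L, 50L),
                                 flag = c(0L, 1024L, 256L, 2048L, 4L)),
                      c(chr1 = 1000))
  tr <- parse_alignments(p, asm)
  expect_equal(sum(tr$rd_100$values$chr1), 1)

  # unknown chromosome counted and skipped; chr-prefix normalized
  p2 <- write_test_sam(data.frame(chrom = c("1", "weird"), pos = c(10L, 10L)),
                       c("1" = 1000, weird = 1000))
  asm2 <- synthetic_assembly(c(chr1 = 1000))
  tr2 <- parse_alignments(p2, asm2)
  expect_equal(sum(tr2$rd_100$values$chr1), 1)
  expect_equal(tr2$stats$skipped_unknown_chrom, 1L)

  # unsorted input rejected
  p3 <- write_test_sam(data.frame(chrom = "chr1", pos = c(500L, 10L)),
                       c(chr1 = 1000))
  expect_error(suppressWarnings(parse_alignments(p3, asm)), "sort")
})

test_that("fit_rd_stats recovers the diploid peak from a histogram fit", {
  set.seed(11)
  v <- rpois(1e5, 300)
  asm <- synthetic_assembly(c(chr1 = 1e5 * 1000))
  trk <- make_track(v, bin_size = 1000L)
  gc <- gc_per_bin(asm, 1000)
  st <- fit_rd_stats(trk, gc, asm)
  expect_lt(abs(st$m - 300) / 300, 0.01)
  expect_lt(abs(st$s - sqrt(300)) / sqrt(300), 0.15)

  # constant signal: m exact, s = 0 with warning
  trk2 <- make_track(rep(50, 500), bin_size = 1000L)
  asm2 <- synthetic_assembly(c(chr1 = 500 * 1000))
  expect_warning(st2 <- fit_rd_stats(trk2, gc_per_bin(asm2, 1000), asm2),
                 "degenerate")
  expect_equal(st2$m, 50)
  expect_equal(st2$s, 0)

  expect_error(fit_rd_stats(make_track(rpois(50, 100), 1000L),
                            gc_per_bin(synthetic_assembly(c(chr1 = 5e4)), 1000),
                            synthetic_assembly(c(chr1 = 5e4))),
               "too few")
})

test_that("per-GC-class means recover stratified levels within 2%", {
  # two GC classes with true means 200 and 400
  set.seed(12)
  n <- 4000
  gc_class <- rep(c(30, 70), each = n / 2)
  v <- rpois(n, ifelse(gc_class == 30, 200, 400))
  trk <- make_track(v, bin_size = 1000L)
  gc <- make_track(gc_class, bin_size = 1000L)
  asm <- synthetic_assembly(c(chr1 = n * 1000))
  st <- fit_rd_stats(trk, gc, asm)
  expect_lt(abs(st$m_gc[31] - 200) / 200, 0.02)
  expect_lt(abs(st$m_gc[71] - 400) / 400, 0.02)
})

test_that("gc_correct equalizes a constructed 2x bias and preserves the mean", {
  set.seed(13)
  n <- 4000
  gc_class <- rep(c(30, 70), times = n / 2)
  v <- rpois(n, ifelse(gc_class == 30, 300, 600))
  trk <- make_track(v, bin_size = 1000L)
  gc <- make_track(gc_class, bin_size = 1000L)
  asm <- synthetic_assembly(c(chr1 = n * 1000))
  st <- fit_rd_stats(trk, gc, asm)
  corr <- gc_correct(trk, st, gc)
  m_lo <- mean(corr$values$chr1[gc_class == 30])
  m_hi <- mean(corr$values$chr1[gc_class == 70])
  expect_lt(abs(m_lo - m_hi) / m_lo, 0.02)
  # corrected autosomal mean equals m within 0.5%
  expect_lt(abs(mean(corr$values$chr1) - st$m) / st$m, 0.005)

  # uniform GC: correction is the identity up to the m/m_gc scale
  v2 <- rpois(1000, 300)
  trk2 <- make_track(v2, bin_size = 1000L)
  gc2 <- make_track(rep(45, 1000), bin_size = 1000L)
  asm2 <- synthetic_assembly(c(chr1 = 1e6))
  st2 <- fit_rd_stats(trk2, gc2, asm2)
  corr2 <- gc_correct(trk2, st2, gc2)
  expect_equal(corr2$values$chr1 / v2,
               rep(st2$m / mean(v2), 1000), tolerance = 1e-12)
  expect_equal(corr2$values$chr1[v2 == 0], numeric(sum(v2 == 0)))

  # bins in undefined GC classes are flagged, not divided
  gc3 <- make_track(c(rep(45, 999), 90), bin_size = 1000L)
  st3 <- fit_rd_stats(trk2, gc3, asm2)
  corr3 <- gc_correct(trk2, st3, gc3)
  expect_true(corr3$uncorrected$chr1[1000])
  expect_equal(corr3$values$chr1[1000], v2[1000])
})
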
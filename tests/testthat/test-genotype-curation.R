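# genotype_curation: region genotyping, filtering, merging, annotation.

test_that("genotype_region implements the weighted copy-number formula", {
  # constant track: any whole-bin region returns exactly CN = 2
  trk <- make_track(rep(250, 1000), 10000L)
  asm <- synthetic_assembly(c(chr1 = 1e7))
  gt <- genotype_region("chr1:2000001-3000000", trk, asm)
  expect_identical(gt$copy_number, 2)

  # region covering exactly half of its first bin: weight 0.5
  v <- rep(100, 100); v[11] <- 200
  trk2 <- make_track(v, 10000L)
  asm2 <- synthetic_assembly(c(chr1 = 1e6))
  # region starts at the midpoint of bin 11 (bin 11 spans 100001-110000)
  gt2 <- genotype_region("chr1:105001-200000", trk2, asm2)
  manual <- (200 * 0.5 + 100 * 9) / 9.5
  expect_equal(gt2$copy_number, 2 * manual / mean(v))

  expect_error(genotype_region("chr1:100-150", trk2, asm2), "smaller")
  expect_error(genotype_region("chrQ:1-10000", trk2, asm2), "unknown")
})

test_that("a planted half-depth region genotypes near CN 1", {
  set.seed(51)
  m <- 3000
  v <- rnorm(2000, m, sqrt(m))
  v[1001:1100] <- rnorm(100, m / 2, sqrt(m / 2))
  trk <- make_track(v, 10000L)
  asm <- synthetic_assembly(c(chr1 = 2e7))
  gt <- genotype_region("chr1:10000001-11000000", trk, asm)
  expect_lt(abs(gt$copy_number - 1), 0.05)
  # whole-genome CN on unbiased diploid data is 2 within 1%
  set.seed(52)
  trk2 <- make_track(rnorm(2000, m, sqrt(m)), 10000L)
  gt2 <- genotype_region("chr1:1-20000000", trk2, asm)
  expect_lt(abs(gt2$copy_number - 2), 0.02)
})

test_that("BAF p-value separates balanced from imbalanced regions", {
  asm <- synthetic_assembly(c(chr1 = 1e4))
  mk <- function(alt, depth) data.frame(
    chrom = "chr1", pos = seq_along(alt) * 10L, ref = "A", alt = "G",
    ref_count = depth - alt, alt_count = alt, qual = 99, gt = "het",
    dp = depth, in_mask = TRUE, stringsAsFactors = FALSE)

  # balanced null: p >= 0.05 in >= 90% of replicates
  hits <- 0L
  for (seed in 1:30) {
    set.seed(seed + 500)
    bl <- bin_likelihood(mk(rbinom(20, 30, 0.5), 30), 10000, asm)
    if (baf_pvalue_region(bl, "chr1:1-10000") >= 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 27L)

  # 40 hets at the 2/3-1/3 duplication split: overwhelming rejection
  set.seed(53)
  alt <- rbinom(40, 30, sample(c(1/3, 2/3), 40, replace = TRUE))
  bl2 <- bin_likelihood(mk(alt, 30), 10000, asm)
  expect_lt(baf_pvalue_region(bl2, "chr1:1-10000"), 1e-6)

  # ML exactly at 0.5 gives p-value 1
  bl3 <- bin_likelihood(mk(c(15, 15), 30), 10000, asm)
  expect_equal(bl3$ml_baf$chr1[1], 0.5)
  expect_identical(baf_pvalue_region(bl3, "chr1:1-10000"), 1)

  # region whose bins are all empty: NA sentinel
  asm2 <- synthetic_assembly(c(chr1 = 2e4))
  bl4 <- bin_likelihood(mk(c(15, 15), 30), 10000, asm2)
  expect_true(is.na(baf_pvalue_region(bl4, "chr1:10001-20000")))
})

test_that("filter_calls applies the five parameters conjunctively", {
  calls <- make_calls(start = c(1, 1, 1, 1, 1) * 1000,
                      end = 1000 + c(500, 2e3, 5e4, 1e5, 2e6) - 1)
  expect_equal(nrow(filter_calls(calls)), 5L)            # no thresholds
  f <- filter_calls(calls, size_range = c(1e3, 1e6))
  expect_equal(nrow(f), 3L)
  expect_equal(attr(f, "removed")[["size"]], 2L)

  calls$q0 <- c(0.1, 0.5, 0.6, 0.2, 0.9)
  f2 <- filter_calls(calls, q0_max = 0.5)
  expect_equal(f2$q0, c(0.1, 0.5, 0.2))                  # > 0.5 removed

  # idempotence
  f3 <- filter_calls(calls, size_range = c(1e3, 1e6), q0_max = 0.5,
                     e_val1_max = 0.05, pN_max = 0.5, dG_min = 100)
  f4 <- filter_calls(f3, size_range = c(1e3, 1e6), q0_max = 0.5,
                     e_val1_max = 0.05, pN_max = 0.5, dG_min = 100)
  expect_equal(as.data.frame(f3), as.data.frame(f4), ignore_attr = TRUE)
})

test_that("merge_calls enforces strict >50% reciprocal overlap", {
  # exact 0.5 overlap fraction on both sides: NOT merged
  a <- make_calls(100, 199)
  b <- make_calls(150, 249)
  m <- merge_calls(list(s1 = a, s2 = b))
  expect_length(m, 2L)

  # 80% reciprocal overlap: merged, intersection (120, 199)
  b2 <- make_calls(120, 219)
  m2 <- merge_calls(list(s1 = a, s2 = b2))
  expect_length(m2, 1L)
  expect_equal(m2[[1]]$start, 120)
  expect_equal(m2[[1]]$end, 199)
  expect_setequal(m2[[1]]$samples, c("s1", "s2"))

  # identical calls collapse to one merged call
  m3 <- merge_calls(list(s1 = a, s2 = make_calls(100, 199)))
  expect_length(m3, 1L)
  expect_equal(m3[[1]]$start, 100)
  expect_equal(m3[[1]]$end, 199)
})

test_that("merging is order-independent and uses each call once", {
  set.seed(54)
  mk_sample <- function(offsets) {
    starts <- c(1000, 5000, 9000) + offsets
    make_calls(starts, starts + c(800, 900, 700))
  }
  s1 <- mk_sample(c(0, 0, 0))
  s2 <- mk_sample(c(50, -60, 30))
  s3 <- mk_sample(c(-40, 20, 0))
  mA <- merge_calls(list(a = s1, b = s2, c = s3))
  mB <- merge_calls(list(c = s3, a = s1, b = s2))
  expect_length(mA, 3L)
  groupsA <- lapply(mA, function(g) sort(paste(g$samples, g$calls$start)))
  groupsB <- lapply(mB, function(g) sort(paste(g$samples, g$calls$start)))
  expect_setequal(groupsA, groupsB)
  # every input call appears in at most one merged call
  used <- do.call(rbind, lapply(mA, function(g) g$calls[, c("sample", "start")]))
  expect_equal(nrow(used), nrow(unique(used)))
  expect_equal(nrow(used), 9L)
})

test_that("merged groups are genotyped in the intersection region", {
  trk <- make_track(rep(300, 200), 10000L)
  asm <- synthetic_assembly(c(chr1 = 2e6))
  ctx <- list(rd = trk, assembly = asm)
  a <- make_calls(100001, 300000)
  b <- make_calls(120001, 310000)
  m <- merge_calls(list(s1 = a, s2 = b),
                   contexts = list(s1 = ctx, s2 = ctx))
  expect_length(m, 1L)
  expect_equal(m[[1]]$genotypes$s1$region, "chr1:120001-300000")
  expect_equal(m[[1]]$genotypes$s2$copy_number, 2)
})

test_that("annotate_calls tags all four gene-call relations", {
  genes <- data.frame(
    name = c("GIN", "GCOV", "GL", "GR", "GOUT"),
    id = paste0("ENSG", 1:5), chrom = "chr1",
    start = c(1500, 500, 800, 1900, 5000),
    end = c(1700, 3000, 1200, 2500, 6000))
  calls <- make_calls(1000, 2000)
  ann <- annotate_calls(calls, genes)$annotation
  expect_match(ann, "GIN\\|ENSG1\\|inside")
  expect_match(ann, "GCOV\\|ENSG2\\|covering")
  expect_match(ann, "GL\\|ENSG3\\|intersects-left-breakpoint")
  expect_match(ann, "GR\\|ENSG4\\|intersects-right-breakpoint")
  expect_no_match(ann, "GOUT")
})
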
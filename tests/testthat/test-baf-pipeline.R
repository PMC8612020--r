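# baf_pipeline: variant ingestion, masking, BAF/MAF, likelihoods, DP proxy.

test_that("parse_variants admits SNPs and single-letter indels with counts", {
  sites_df <- data.frame(
    chrom = "chr1", pos = c(100L, 200L, 300L, 400L, 500L),
    ref = c("A", "C", "ACT", "G", "GA"),
    alt = c("G", "T", "A", "GT", "G"),
    gt = c("0/1", "1/1", "0/1", "0/1", "0/1"),
    ad_ref = c(7L, 0L, 5L, 6L, 4L), ad_alt = c(5L, 9L, 5L, 6L, 8L))
  p <- write_test_vcf(sites_df, c(chr1 = 10000))
  sites <- parse_variants(p)
  # the 3-bp deletion is ignored; SNVs and 1-bp indels admitted
  expect_equal(nrow(sites), 4L)
  expect_equal(sites$pos, c(100L, 200L, 400L, 500L))
  expect_equal(sites$ref_count[1], 7)
  expect_equal(sites$alt_count[1], 5)
  expect_equal(sites$gt, c("het", "hom", "het", "het"))
  expect_equal(attr(sites, "skipped")[["not_snp_indel"]], 1L)

  # hom with AD=0,9 is retained (counts feed per-bin tallies, not L)
  expect_equal(sites$ref_count[2], 0)
  expect_equal(sites$alt_count[2], 9)
})

test_that("parse_variants skips unusable genotypes and tallies them", {
  sites_df <- data.frame(
    chrom = "chr1", pos = c(100L, 200L, 300L),
    ref = "A", alt = "G",
    gt = c("0/0", "./.", "0/1"),
    ad_ref = c(5L, 5L, 5L), ad_alt = c(5L, 5L, 5L))
  p <- write_test_vcf(sites_df, c(chr1 = 10000))
  sites <- parse_variants(p)
  expect_equal(nrow(sites), 1L)
  expect_equal(attr(sites, "skipped")[["no_genotype"]], 2L)
})

test_that("strict-mask flags use the half-open boundary convention", {
  mask <- load_strict_mask(data.frame(chrom = "chr1", start = 10, end = 20))
  sites <- data.frame(chrom = "chr1", pos = c(15L, 20L, 21L),
                      ref = "A", alt = "G", ref_count = 5, alt_count = 5,
                      qual = 99, gt = "het", dp = 10, in_mask = NA)
  out <- apply_strict_mask(sites, mask)
  expect_equal(out$in_mask, c(TRUE, TRUE, FALSE))
  empty <- load_strict_mask(data.frame(chrom = character(),
                                       start = numeric(), end = numeric()))
  expect_equal(apply_strict_mask(sites, empty)$in_mask, rep(FALSE, 3))
})

test_that("baf and maf follow their defining formulas", {
  s <- data.frame(ref_count = c(5, 8, 9, 0), alt_count = c(5, 0, 3, 0))
  expect_equal(baf(s), c(0.5, 0, 0.25, NA))
  expect_equal(maf(s), c(0.5, 0, 0.25, NA))
})

test_that("site likelihood matches a brute-force grid oracle", {
  # closed-form symmetrized kernel evaluated naively on a 1001-point grid
  oracle <- function(alt, ref, grid)
    grid^alt * (1 - grid)^ref + grid^ref * (1 - grid)^alt
  grid <- baf_grid(1001L)
  for (counts in list(c(10, 5), c(3, 9), c(17, 17), c(0, 12), c(25, 8))) {
    ours <- site_likelihood(counts[1], counts[2], grid)
    ref <- oracle(counts[1], counts[2], grid)
    expect_equal(which.max(ours), which.max(ref))
    expect_equal(ours, ref / max(ref), tolerance = 1e-9)
  }
  # alt=10, ref=5: argmax near 1/3 on the restricted [0, 0.5] range (the
  # mirrored term's tail shifts the mode slightly above the naive 1/3)
  am <- grid[which.max(site_likelihood(10, 5, grid))]
  expect_lt(abs(am - 1 / 3), 0.02)
  # alt=ref: restricted maximum at the boundary 0.5
  expect_equal(grid[which.max(site_likelihood(7, 7, grid))], 0.5)
  # ref/alt swap symmetry is exact
  expect_identical(site_likelihood(10, 5, grid), site_likelihood(5, 10, grid))
})

make_het_sites <- function(pos, alt, ref, chrom = "chr1") {
  data.frame(chrom = chrom, pos = pos, ref = "A", alt = "G",
             ref_count = ref, alt_count = alt, qual = 99, gt = "het",
             dp = ref + alt, in_mask = TRUE, stringsAsFactors = FALSE)
}

test_that("bin likelihood is a max-normalized product over in-mask hets", {
  asm <- synthetic_assembly(c(chr1 = 3e4))
  # single site: bin likelihood equals the site's own normalized curve
  s1 <- make_het_sites(5000L, 10, 5)
  bl <- bin_likelihood(s1, 10000, asm)
  expect_equal(bl$lik$chr1[1, ], site_likelihood(10, 5, bl$grid))
  expect_equal(max(bl$lik$chr1[1, ]), 1)
  expect_equal(bl$n_het$chr1, c(1L, 0L, 0L))
  expect_true(is.na(bl$ml_baf$chr1[2]))

  # hom sites and off-mask sites are counted but excluded from L
  s2 <- rbind(s1, make_het_sites(5100L, 12, 0))
  s2$gt[2] <- "hom"
  s3 <- rbind(s2, make_het_sites(5200L, 20, 1))
  s3$in_mask[3] <- FALSE
  bl3 <- bin_likelihood(s3, 10000, asm)
  expect_equal(bl3$lik$chr1[1, ], bl$lik$chr1[1, ])
  expect_equal(bl3$n_hom$chr1[1], 1L)

  # product is order-independent
  set.seed(41)
  pos <- sample.int(9000, 30) + 500L
  alt <- rbinom(30, 30, 0.5)
  sA <- make_het_sites(pos, alt, 30 - alt)
  sB <- sA[sample.int(30), ]
  blA <- bin_likelihood(sA, 10000, asm)
  blB <- bin_likelihood(sB, 10000, asm)
  expect_equal(blA$lik$chr1, blB$lik$chr1, tolerance = 1e-12)

  # global ref/alt swap leaves bin likelihood unchanged
  sw <- sA; sw$ref_count <- sA$alt_count; sw$alt_count <- sA$ref_count
  expect_equal(bin_likelihood(sw, 10000, asm)$lik$chr1, blA$lik$chr1,
               tolerance = 1e-12)
})

test_that("ML BAF lands on 0.5 for balanced bins and 1/3 for duplications", {
  asm <- synthetic_assembly(c(chr1 = 1e4))
  set.seed(42)
  alt <- rbinom(20, 30, 0.5)
  bl <- bin_likelihood(make_het_sites(sort(sample.int(1e4, 20)), alt,
                                      30 - alt), 10000, asm)
  expect_equal(bl$ml_baf$chr1[1], 0.5)

  # one-haplotype duplication: per-site fraction 2/3 or 1/3
  set.seed(43)
  f <- sample(c(1 / 3, 2 / 3), 40, replace = TRUE)
  alt2 <- rbinom(40, 30, f)
  bl2 <- bin_likelihood(make_het_sites(sort(sample.int(1e4, 40)), alt2,
                                       30 - alt2), 10000, asm)
  step <- bl2$grid[2] - bl2$grid[1]
  expect_lte(abs(bl2$ml_baf$chr1[1] - 1 / 3), step + 1e-12)
})

test_that("ML BAF concentrates as het count grows", {
  asm <- synthetic_assembly(c(chr1 = 1e4))
  p_true <- 0.3
  err <- sapply(c(25, 100), function(n) {
    errs <- numeric(40)
    for (r in 1:40) {
      set.seed(1000 + 7 * r + n)
      alt <- rbinom(n, 40, sample(c(p_true, 1 - p_true), n, replace = TRUE))
      bl <- bin_likelihood(make_het_sites(seq_len(n) * 10L, alt, 40 - alt),
                           10000, asm, grid_points = 501L)
      errs[r] <- abs(bl$ml_baf$chr1[1] - p_true)
    }
    mean(errs)
  })
  # quadrupling n halves the error, within a factor of 2
  expect_lte(err[2] / err[1], 1.0)
  expect_gte(err[2] / err[1], 0.25 / 2)
})

test_that("mask filtering restores binomial BAF dispersion", {
  asm <- synthetic_assembly(c(chr1 = 1e6))
  mask <- load_strict_mask(data.frame(chrom = "chr1", start = 0, end = 5e5))
  d <- 100
  set.seed(44)
  n_good <- 2000
  good <- make_het_sites(sort(sample.int(5e5, n_good)),
                         rbinom(n_good, d, 0.5), 0)
  good$ref_count <- d - good$alt_count
  good$dp <- d
  n_bad <- 100   # 5% outliers, only outside P regions
  bad <- make_het_sites(5e5 + sort(sample.int(5e5, n_bad)),
                        rbinom(n_bad, d, rbeta(n_bad, 0.2, 0.2)), 0)
  bad$ref_count <- d - bad$alt_count
  bad$dp <- d
  sites <- apply_strict_mask(rbind(good, bad), mask)
  kept <- sites[sites$in_mask, ]
  expect_equal(nrow(kept), n_good)
  v <- var(baf(kept))
  expect_lt(abs(v - 0.25 / d) / (0.25 / d), 0.10)
})

test_that("rd_from_variant_depth averages DP and flags empty bins", {
  asm <- synthetic_assembly(c(chr1 = 3e4))
  s <- make_het_sites(c(1000L, 2000L, 25000L), c(15, 16, 20), c(15, 16, 25))
  trk <- rd_from_variant_depth(s, 10000, asm)
  expect_equal(trk$values$chr1, c(31, NA, 45))

  s0 <- make_het_sites(100L, 0, 0); s0$dp <- NA
  expect_error(rd_from_variant_depth(s0, 10000, asm), "depth")
})

test_that("DP proxy tracks true coverage ratios at large bins", {
  asm <- synthetic_assembly(c(chr1 = 1e6))
  ev <- truth_events("duplication", "chr1", 500001, 1e6)
  p <- simulate_vcf(asm, tempfile(fileext = ".vcf"), depth = 30,
                    events = ev, seed = 45)
  sites <- parse_variants(p)
  sites$in_mask <- TRUE
  trk <- rd_from_variant_depth(sites, 10000, asm)
  v <- trk$values$chr1
  ratio <- mean(v[51:100], na.rm = TRUE) / mean(v[1:50], na.rm = TRUE)
  expect_lt(abs(ratio - 1.5), 0.05)
})
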
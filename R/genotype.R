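# Region genotyping: copy number from depth, plus the optional statistics
# block (e-value, q0, pN, ML BAF level, het/hom counts, BAF p-value).

region_bin_weights <- function(start, end, bin_size, n_bins) {
  b1 <- max(1L, pos_to_bin(start, bin_size))
  b2 <- min(n_bins, pos_to_bin(end, bin_size))
  idx <- b1:b2
  span <- bin_span(idx, bin_size)
  ov_start <- pmax(start, span[, "start"])
  ov_end <- pmin(end, span[, "end"])
  list(idx = idx, w = (ov_end - ov_start + 1) / bin_size)
}

autosomal_mean_rd <- function(rd, assembly) {
  vals <- numeric(0)
  for (ch in names(rd$values)) {
    if (!isTRUE(assembly$autosome[[ch]])) next
    v <- rd$values[[ch]]
    frac <- bin_coverage_fraction(rd, ch)
    vals <- c(vals, v[!is.na(v) & frac == 1])
  }
  if (length(vals) == 0L) stop("no usable autosomal bins")
  mean(vals)
}

#' Genotype a genomic region
#'
#' Copy number is twice the ratio of the region's overlap-weighted mean
#' depth to the mean autosomal depth: bins only partially covered by the
#' region enter the mean with weight equal to their overlap fraction.
#' With an `rd_stats` the Gaussian-tail e-value is reported; with 100-bp
#' q0/raw tracks the q0 fraction; with a `bin_likelihood` the ML BAF
#' level, het/hom counts and the BAF p-value (likelihood-ratio test of
#' balanced alleles, see [baf_pvalue_region()]).
#'
#' @param region region string "chr:start-end" (1-based inclusive) or a
#'   list with chrom/start/end.
#' @param rd corrected-depth `binned_track`.
#' @param assembly `genome_assembly`.
#' @param stats optional `rd_stats`.
#' @param q0_100,rd_100 optional 100-bp tracks for q0.
#' @param baf optional `bin_likelihood` at any bin size.
#' @return a `genotype_result` list: region, copy_number, e_value, q0, pN,
#'   baf_level, n_het, n_hom, baf_pvalue.
#' @export
genotype_region <- function(region, rd, assembly, stats = NULL,
                            q0_100 = NULL, rd_100 = NULL, baf = NULL) {
  r <- if (is.character(region)) parse_region(region) else region
  ch <- normalize_chrom(r$chrom, assembly$chroms)
  if (is.na(ch)) stop("unknown chromosome: ", r$chrom)
  if (r$end - r$start + 1 < RESOURCE_BIN)
    stop("region smaller than one ", RESOURCE_BIN, "-bp bin")
  v <- rd$values[[ch]]
  rw <- region_bin_weights(r$start, r$end, rd$bin_size, length(v))
  x <- v[rw$idx]; w <- rw$w
  ok <- !is.na(x)
  wmean <- sum(x[ok] * w[ok]) / sum(w[ok])
  cn <- 2 * wmean / autosomal_mean_rd(rd, assembly)

  e_value <- if (!is.null(stats))
    region_tail_pvalue(x, stats, stats$n_bins_genome) else NA_real_
  q0 <- region_q0(q0_100, rd_100, ch, r$start, r$end)
  pN <- region_pn(assembly, ch, r$start, r$end)

  baf_level <- n_het <- n_hom <- baf_p <- NA_real_
  if (!is.null(baf)) {
    bl <- region_baf_pool(baf, ch, r$start, r$end)
    n_het <- bl$n_het; n_hom <- bl$n_hom
    if (!is.null(bl$loglik)) {
      baf_level <- baf$grid[grid_argmax(bl$loglik)]
      baf_p <- baf_lrt_pvalue(bl$loglik, baf$grid)
    }
  }
  structure(list(
    region = format_region(ch, r$start, r$end),
    copy_number = cn, e_value = e_value, q0 = q0, pN = pN,
    baf_level = baf_level, n_het = n_het, n_hom = n_hom,
    baf_pvalue = baf_p), class = "genotype_result")
}

#' @export
print.genotype_result <- function(x, ...) {
  cat(sprintf("%s  CN = %.3f  e-value = %.3g  q0 = %.3g  pN = %.3g\n",
              x$region, x$copy_number, x$e_value, x$q0, x$pN))
  if (!is.na(x$baf_level))
    cat(sprintf("  BAF level = %.3f  (hets %d, homs %d, BAF p = %.3g)\n",
                x$baf_level, x$n_het, x$n_hom, x$baf_pvalue))
  invisible(x)
}

# Pool per-bin log-likelihoods over the bins a region overlaps.
region_baf_pool <- function(baf, chrom, start, end) {
  lik <- baf$lik[[chrom]]
  if (is.null(lik)) return(list(loglik = NULL, n_het = 0L, n_hom = 0L))
  b1 <- max(1L, pos_to_bin(start, baf$bin_size))
  b2 <- min(nrow(lik), pos_to_bin(end, baf$bin_size))
  idx <- b1:b2
  nonempty <- idx[!is.na(lik[idx, 1])]
  loglik <- NULL
  if (length(nonempty)) {
    lmat <- log(lik[nonempty, , drop = FALSE])
    loglik <- colSums(lmat)
  }
  list(loglik = loglik,
       n_het = sum(baf$n_het[[chrom]][idx]),
       n_hom = sum(baf$n_hom[[chrom]][idx]))
}

# Boundary-corrected likelihood-ratio p-value for H0: p = 0.5.
baf_lrt_pvalue <- function(loglik, grid) {
  i_max <- grid_argmax(loglik)
  if (grid[i_max] >= 0.5) return(1)
  stat <- 2 * (loglik[i_max] - loglik[length(grid)])
  0.5 * pchisq(stat, df = 1, lower.tail = FALSE)
}

#' BAF balance p-value for a region
#'
#' Likelihood-ratio test of the balanced-allele null p = 0.5 against the
#' maximum-likelihood allele fraction, over the pooled likelihood of all
#' nonempty bins in the region. The statistic 2(logL(p-hat) - logL(0.5))
#' is referred to the chi-square(1) tail, halved because the null sits on
#' the boundary of the `[0, 0.5]` parameter range; p-hat = 0.5 returns 1.
#'
#' @param baf a `bin_likelihood`.
#' @param region region string or list with chrom/start/end.
#' @return p-value in `[0, 1]`; NA if every bin in the region is empty.
#' @export
baf_pvalue_region <- function(baf, region) {
  r <- if (is.character(region)) parse_region(region) else region
  pool <- region_baf_pool(baf, r$chrom, r$start, r$end)
  if (is.null(pool$loglik)) return(NA_real_)
  baf_lrt_pvalue(pool$loglik, baf$grid)
}
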
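# Global read-depth statistics and GC-bias correction.
#
# The diploid level (m) and its spread (s) are estimated by fitting a
# Gaussian to the histogram of autosomal bin counts rather than by raw
# moments: zero-inflated bins (gaps), CNV bins and long tails then perturb
# the estimate far less, since only the shape of the diploid peak matters.

# Gaussian fit to the histogram of a sample of bin counts.
fit_gaussian_hist <- function(v, nbreaks = 101L) {
  med <- median(v)
  spread <- stats::mad(v)
  if (spread == 0) spread <- sd(v)
  if (spread == 0) {
    warning("degenerate constant RD signal; s = 0")
    return(list(m = med, s = 0))
  }
  lo <- max(min(v), med - 6 * spread)
  hi <- min(max(v), med + 6 * spread)
  br <- seq(lo, hi, length.out = nbreaks + 1L)
  h <- graphics::hist(v[v >= lo & v <= hi], breaks = br, plot = FALSE)
  mids <- h$mids
  counts <- h$counts
  mu0 <- mids[which.max(counts)]
  s0 <- min(spread, (hi - lo) / 4)
  a0 <- max(counts)
  w <- mids[2] - mids[1]
  obj <- function(par) {
    a <- par[1]; mu <- par[2]; s <- par[3]
    sum((counts - a * exp(-(mids - mu)^2 / (2 * s^2)))^2)
  }
  fit <- optim(c(a0, mu0, s0), obj, method = "L-BFGS-B",
               lower = c(1e-9, lo, w / 2), upper = c(Inf, hi, hi - lo),
               control = list(maxit = 2000))
  list(m = fit$par[2], s = fit$par[3])
}

#' Fit global and per-GC-class read-depth statistics
#'
#' Estimates the diploid read-depth level `m` and standard deviation `s`
#' from a Gaussian fit to the histogram of autosomal bin counts, and the
#' mean depth `m_gc` of autosomal bins in each integer GC% class. `m_gc`
#' drives GC correction; classes with fewer than `min_class_bins` bins are
#' left undefined (their bins stay uncorrected).
#'
#' Partial terminal chromosome bins and bins without usable GC (all-N) are
#' excluded from the fit.
#'
#' @param rd a `binned_track` of read counts.
#' @param gc matching `binned_track` of integer GC% (from [gc_per_bin()]).
#' @param assembly a `genome_assembly` (autosome flags).
#' @param min_class_bins minimum bins per GC class for `m_gc` (default 2).
#' @param min_bins minimum usable autosomal bins overall (default 100).
#' @return an `rd_stats` object: `m`, `s`, `m_gc` (length-101 vector
#'   indexed by GC% 0..100, NA where undefined), `n_bins_genome`.
#' @export
fit_rd_stats <- function(rd, gc, assembly, min_class_bins = 2L,
                         min_bins = 100L) {
  stopifnot(rd$bin_size == gc$bin_size)
  vals <- numeric(0); gcs <- numeric(0)
  for (ch in names(rd$values)) {
    if (!isTRUE(assembly$autosome[[ch]])) next
    v <- rd$values[[ch]]; g <- gc$values[[ch]]
    frac <- bin_coverage_fraction(rd, ch)
    use <- !is.na(v) & !is.na(g) & frac == 1
    vals <- c(vals, v[use]); gcs <- c(gcs, g[use])
  }
  if (length(vals) < min_bins)
    stop("too few usable autosomal bins (", length(vals), " < ",
         min_bins, ")")
  fit <- fit_gaussian_hist(vals)
  m_gc <- rep(NA_real_, 101L)
  tab <- table(gcs)
  for (cls in as.integer(names(tab))) {
    if (tab[[as.character(cls)]] >= min_class_bins)
      m_gc[cls + 1L] <- mean(vals[gcs == cls])
  }
  structure(list(m = fit$m, s = fit$s, m_gc = m_gc,
                 n_bins_genome = sum(lengths(rd$values))),
            class = "rd_stats")
}

#' @export
print.rd_stats <- function(x, ...) {
  cat(sprintf("rd_stats: m = %.2f, s = %.2f, %d GC classes defined\n",
              x$m, x$s, sum(!is.na(x$m_gc))))
  invisible(x)
}

#' Correct binned read depth for GC bias
#'
#' Each bin is scaled by `m / m_gc(GC%)`, the ratio of the global diploid
#' level to the mean level of its GC class, so that after correction all
#' GC classes share the same expected depth. Bins with unusable GC (all N)
#' or a sparse GC class are left uncorrected and flagged.
#'
#' @param rd a `binned_track` of read counts.
#' @param stats an `rd_stats` from [fit_rd_stats()].
#' @param gc matching GC% `binned_track`.
#' @return a `binned_track` of corrected depth; element `uncorrected`
#'   carries per-chromosome logical flags.
#' @export
gc_correct <- function(rd, stats, gc) {
  stopifnot(rd$bin_size == gc$bin_size)
  out <- rd$values
  flags <- list()
  for (ch in names(rd$values)) {
    v <- rd$values[[ch]]; g <- gc$values[[ch]]
    mgc <- rep(NA_real_, length(v))
    ok <- !is.na(g)
    mgc[ok] <- stats$m_gc[g[ok] + 1L]
    usable <- !is.na(mgc) & mgc > 0
    corr <- v
    corr[usable] <- v[usable] * stats$m / mgc[usable]
    out[[ch]] <- corr
    flags[[ch]] <- !usable
  }
  trk <- binned_track(rd$bin_size, out, rd$lengths)
  trk$uncorrected <- flags
  trk
}

#' Rebin, GC-correct and fit statistics in one step
#'
#' The standard per-bin-size preparation: rebin the 100-bp depth track,
#' fit raw statistics, correct GC bias, then refit (m, s) on the
#' corrected signal — on strongly GC-structured genomes the raw histogram
#' is multi-modal and only the corrected one has a clean diploid peak.
#'
#' @param rd_100 100-bp depth `binned_track` from [parse_alignments()].
#' @param assembly `genome_assembly`.
#' @param bin_size target bin size (multiple of 100).
#' @param ... passed to [fit_rd_stats()].
#' @return list: `rd` (rebinned raw), `gc` (GC% track), `corrected`
#'   (GC-corrected track), `stats` (`rd_stats` refit on the corrected
#'   signal), `stats_raw`.
#' @export
prepare_rd <- function(rd_100, assembly, bin_size, ...) {
  rd <- if (bin_size == rd_100$bin_size) rd_100 else rebin(rd_100, bin_size)
  gc <- gc_per_bin(assembly, bin_size)
  stats_raw <- fit_rd_stats(rd, gc, assembly, ...)
  corrected <- gc_correct(rd, stats_raw, gc)
  stats <- fit_rd_stats(corrected, gc, assembly, ...)
  stats$m_gc <- stats_raw$m_gc
  list(rd = rd, gc = gc, corrected = corrected, stats = stats,
       stats_raw = stats_raw)
}
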
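# Multi-scale mean-shift segmentation of the corrected read-depth signal.
#
# The mean-shift vector at each bin points toward the local mode of the
# joint (position, depth) density; zeros of the vector at density valleys
# mark segment boundaries. The kernel is Gaussian in both coordinates:
# bandwidth h bins in position, and in signal space a depth-dependent
# variance s^2 * level / m (Poisson-like scaling of the fitted global
# spread). Partitioning runs at increasing bandwidths h = 2, 4, ..., 128;
# at each scale, segment bins are replaced by their segment mean and the
# partition is iterated to a fixed point before moving to the next scale.
# A final pass merges adjacent segments whose means are not significantly
# different and refines each surviving boundary by a local least-squares
# search, so that constant input yields a single segment and a true step
# is localized to the bin.

ms_signal_var <- function(level, stats, floor_frac = 0.05) {
  s <- max(stats$s, 1e-12)
  m <- max(stats$m, 1e-12)
  s^2 * pmax(level, floor_frac * m) / m
}

# Mean-shift gradient of the working signal w at bandwidth h.
ms_gradient <- function(w, h, stats) {
  n <- length(w)
  grad <- numeric(n)
  D <- min(3L * h, n - 1L)
  sig2 <- ms_signal_var(w, stats)
  for (d in seq_len(D)) {
    kpos <- d * exp(-d^2 / (2 * h^2))
    a <- w[seq_len(n - d)]
    b <- w[seq.int(d + 1L, n)]
    ks <- exp(-(a - b)^2 / (2 * (sig2[seq_len(n - d)] + sig2[seq.int(d + 1L, n)])))
    contrib <- kpos * ks
    grad[seq_len(n - d)] <- grad[seq_len(n - d)] + contrib
    grad[seq.int(d + 1L, n)] <- grad[seq.int(d + 1L, n)] - contrib
  }
  grad
}

# boundaries: sorted vector of split points; a boundary at position k means
# a cut between compact bins k and k+1.
ms_partition_means <- function(x, boundaries) {
  starts <- c(1L, boundaries + 1L)
  ends <- c(boundaries, length(x))
  means <- vapply(seq_along(starts),
                  function(i) mean(x[starts[i]:ends[i]]), numeric(1))
  list(starts = starts, ends = ends, means = means)
}

ms_expand <- function(part) {
  rep(part$means, part$ends - part$starts + 1L)
}

# Two-segment z-test under the Poisson-scaled noise model; used both for
# the merge pass and for significance of adjacent segments.
ms_seg_pvalue <- function(m1, n1, m2, n2, stats) {
  v <- ms_signal_var(m1, stats) / n1 + ms_signal_var(m2, stats) / n2
  if (v <= 0) return(as.numeric(m1 == m2))
  2 * pnorm(-abs(m1 - m2) / sqrt(v))
}

ms_merge_pass <- function(x, boundaries, stats, alpha) {
  if (length(boundaries) == 0L) return(boundaries)
  part <- ms_partition_means(x, boundaries)
  n <- part$ends - part$starts + 1L
  means <- part$means
  k <- length(means)
  p <- vapply(seq_len(k - 1L), function(i)
    ms_seg_pvalue(means[i], n[i], means[i + 1L], n[i + 1L], stats),
    numeric(1))
  repeat {
    if (length(p) == 0L) break
    worst <- which.max(p)
    if (p[worst] < alpha) break
    # merge segments worst and worst+1
    i <- worst
    new_mean <- (means[i] * n[i] + means[i + 1L] * n[i + 1L]) /
      (n[i] + n[i + 1L])
    means[i] <- new_mean
    n[i] <- n[i] + n[i + 1L]
    means <- means[-(i + 1L)]
    n <- n[-(i + 1L)]
    boundaries <- boundaries[-i]
    p <- p[-i]
    if (i > 1L)
      p[i - 1L] <- ms_seg_pvalue(means[i - 1L], n[i - 1L], means[i], n[i],
                                 stats)
    if (i <= length(p))
      p[i] <- ms_seg_pvalue(means[i], n[i], means[i + 1L], n[i + 1L], stats)
  }
  boundaries
}

# Local least-squares refinement of each boundary within +/- window bins.
ms_refine <- function(x, boundaries, window = 8L) {
  if (length(boundaries) == 0L) return(boundaries)
  part <- ms_partition_means(x, boundaries)
  for (i in seq_along(boundaries)) {
    lo <- part$starts[i]
    hi <- part$ends[i + 1L]
    cand <- seq.int(max(lo, boundaries[i] - window),
                    min(hi - 1L, boundaries[i] + window))
    seg <- x[lo:hi]
    sse <- vapply(cand, function(k) {
      left <- seg[seq_len(k - lo + 1L)]
      right <- seg[seq.int(k - lo + 2L, hi - lo + 1L)]
      sum((left - mean(left))^2) + sum((right - mean(right))^2)
    }, numeric(1))
    boundaries[i] <- cand[which.min(sse)]
    part <- ms_partition_means(x, boundaries)
  }
  boundaries
}

#' Segment binned read depth by multi-scale mean shift
#'
#' Produces a tiling segmentation of each chromosome in which adjacent
#' segments have significantly different mean depth. Deterministic for a
#' fixed input and parameter set.
#'
#' @param rd corrected-depth `binned_track`.
#' @param stats `rd_stats` providing the global (m, s).
#' @param exclude optional named list of logical vectors flagging bins to
#'   leave out of the distance computations (all-N bins, sparse GC class);
#'   excluded bins keep their positions so coordinates stay global.
#' @param bandwidths position-space bandwidth schedule, in bins.
#' @param alpha significance level for the adjacent-segment merge test.
#' @param max_iter partition-update iterations per bandwidth.
#' @param refine_window half-width (bins) of the boundary refinement
#'   search; 0 disables refinement.
#' @return data.frame with columns chrom, first_bin, last_bin (1-based,
#'   inclusive, tiling each chromosome) and mean (of usable bins).
#' @export
mean_shift_segment <- function(rd, stats, exclude = NULL,
                               bandwidths = 2L^(1:7), alpha = 1e-5,
                               max_iter = 30L, refine_window = 8L) {
  out <- list()
  for (ch in names(rd$values)) {
    v <- rd$values[[ch]]
    nb <- length(v)
    if (nb == 0L) next
    usable <- !is.na(v)
    if (!is.null(exclude) && !is.null(exclude[[ch]]))
      usable <- usable & !exclude[[ch]]
    idx <- which(usable)
    if (length(idx) == 0L) {
      out[[ch]] <- data.frame(chrom = ch, first_bin = 1L, last_bin = nb,
                              mean = NA_real_)
      next
    }
    x <- v[idx]
    n <- length(x)
    boundaries <- integer(0)
    if (n > 1L && sd(x) > 0) {
      # Boundaries accumulate across scales: a valley found at any
      # bandwidth stays a candidate (larger bandwidths smooth over short
      # events, so small-scale finds must not be erased); the significance
      # merge afterwards removes everything the noise model cannot
      # support.
      w <- x
      for (h in bandwidths[bandwidths < n]) {
        for (it in seq_len(max_iter)) {
          grad <- ms_gradient(w, as.integer(h), stats)
          valleys <- which(grad[-n] < 0 & grad[-1L] > 0)
          nb_new <- sort(unique(c(boundaries, valleys)))
          part <- ms_partition_means(x, nb_new)
          w <- ms_expand(part)
          if (identical(nb_new, boundaries)) break
          boundaries <- nb_new
        }
      }
      boundaries <- ms_merge_pass(x, boundaries, stats, alpha)
      if (refine_window > 0L)
        boundaries <- ms_refine(x, boundaries, as.integer(refine_window))
      boundaries <- ms_merge_pass(x, boundaries, stats, alpha)
    }
    part <- ms_partition_means(x, boundaries)
    # map compact coordinates back to global bin indices; segments absorb
    # flanking excluded bins so the tiling covers the chromosome
    first_g <- idx[part$starts]
    last_g <- c(first_g[-1L] - 1L, nb)
    first_g[1L] <- 1L
    out[[length(out) + 1L]] <- data.frame(
      chrom = ch, first_bin = as.integer(first_g),
      last_bin = as.integer(last_g), mean = part$means,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
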
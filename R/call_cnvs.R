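# CNV calling from a segmentation: segments whose normalized depth falls
# below the deletion threshold or above the duplication threshold become
# candidate calls, adjacent same-type candidates are merged, and each call
# is scored with the full statistics block: e-val1..4 (region-vs-genome
# significance with and without the boundary bins), q0 (zero-mapping-
# quality read fraction), pN (N-base fraction) and dG (distance to the
# nearest assembly gap).

region_t_pvalue <- function(x, mu, stats) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n == 0L) return(NA_real_)
  if (n == 1L || sd(x) == 0) {
    s <- max(stats$s, 1e-12)
    return(2 * pnorm(-abs(mean(x) - mu) / (s / sqrt(n))))
  }
  t.test(x, mu = mu)$p.value
}

region_tail_pvalue <- function(x, stats, n_genome) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n == 0L) return(NA_real_)
  s <- max(stats$s, 1e-12)
  p <- 2 * pnorm(-abs(mean(x) - stats$m) / (s / sqrt(n)))
  min(1, p * n_genome / n)
}

# q0 and pN over a 1-based inclusive region, from the 100-bp tracks.
# Partial 100-bp bins at the region edges are weighted by overlap.
region_q0 <- function(q0_100, rd_100, chrom, start, end) {
  if (is.null(q0_100) || is.null(rd_100)) return(NA_real_)
  b1 <- pos_to_bin(start, RESOURCE_BIN)
  b2 <- pos_to_bin(end, RESOURCE_BIN)
  q <- q0_100$values[[chrom]]
  r <- rd_100$values[[chrom]]
  b2 <- min(b2, length(r))
  tot <- sum(r[b1:b2], na.rm = TRUE)
  if (tot == 0) return(0)
  sum(q[b1:b2], na.rm = TRUE) / tot
}

region_pn <- function(assembly, chrom, start, end) {
  n100 <- assembly$n_100[[chrom]]
  b1 <- pos_to_bin(start, RESOURCE_BIN)
  b2 <- min(pos_to_bin(end, RESOURCE_BIN), length(n100))
  idx <- b1:b2
  w <- rep(1, length(idx))
  span <- bin_span(idx, RESOURCE_BIN)
  w[1] <- (span[1, "end"] - max(start, span[1, "start"]) + 1) / RESOURCE_BIN
  k <- length(idx)
  w[k] <- w[k] * (min(end, span[k, "end"]) - span[k, "start"] + 1) / RESOURCE_BIN
  covered <- sum(w) * RESOURCE_BIN
  sum(n100[idx] * w) / covered
}

#' Call CNVs from a segmentation
#'
#' Segments whose mean depth, normalized to the diploid level, drops below
#' `del_threshold` are deletion candidates; above `dup_threshold`,
#' duplication candidates. Adjacent same-type candidates separated by at
#' most `merge_gap` bins are merged before scoring. normRD is scaled so
#' diploid = 1; e-val1 is a one-sample t-test of region bins against the
#' global mean; e-val2 is the Gaussian tail probability of the region mean
#' under N(m, s/sqrt(n)), Bonferroni-scaled by (genome bins / region bins)
#' and capped at 1; e-val3/4 repeat both without the first and last bin
#' (NA for regions under 3 bins).
#'
#' @param segments segmentation data.frame from [mean_shift_segment()].
#' @param rd corrected-depth `binned_track` the segmentation came from.
#' @param stats `rd_stats`.
#' @param assembly `genome_assembly` (for pN and chromosome bounds).
#' @param gaps optional `gap_set` for dG.
#' @param q0_100,rd_100 optional 100-bp q0 and raw depth tracks for q0.
#' @param del_threshold,dup_threshold normRD cutoffs (defaults 0.75/1.25).
#' @param merge_gap maximum separating bins for candidate merging.
#' @return a data.frame of calls (class `cnv_calls`) with columns type,
#'   chrom, start, end, size, normRD, e_val1..e_val4, q0, pN, dG.
#' @export
call_cnvs <- function(segments, rd, stats, assembly, gaps = NULL,
                      q0_100 = NULL, rd_100 = NULL,
                      del_threshold = 0.75, dup_threshold = 1.25,
                      merge_gap = 1L) {
  bs <- rd$bin_size
  calls <- list()
  for (ch in unique(segments$chrom)) {
    seg <- segments[segments$chrom == ch, , drop = FALSE]
    norm <- seg$mean / stats$m
    type <- ifelse(is.na(norm), "none",
                   ifelse(norm < del_threshold, "deletion",
                          ifelse(norm > dup_threshold, "duplication", "none")))
    cand <- which(type != "none")
    if (length(cand) == 0L) next
    # merge adjacent same-type candidates separated by <= merge_gap bins
    groups <- list()
    cur <- cand[1]
    cur_first <- seg$first_bin[cand[1]]; cur_last <- seg$last_bin[cand[1]]
    cur_type <- type[cand[1]]
    flush <- function(groups, first, last, ty) {
      groups[[length(groups) + 1L]] <- list(first = first, last = last,
                                            type = ty)
      groups
    }
    if (length(cand) > 1L) {
      for (i in cand[-1]) {
        sep <- seg$first_bin[i] - cur_last - 1L
        if (type[i] == cur_type && sep <= merge_gap) {
          cur_last <- seg$last_bin[i]
        } else {
          groups <- flush(groups, cur_first, cur_last, cur_type)
          cur_first <- seg$first_bin[i]; cur_last <- seg$last_bin[i]
          cur_type <- type[i]
        }
      }
    }
    groups <- flush(groups, cur_first, cur_last, cur_type)

    v <- rd$values[[ch]]
    chrom_len <- if (!is.null(rd$lengths)) rd$lengths[[ch]] else length(v) * bs
    for (g in groups) {
      bins <- v[g$first:g$last]
      start <- (g$first - 1L) * bs + 1
      end <- min(g$last * bs, chrom_len)
      inner <- if (g$last - g$first + 1L >= 3L)
        v[(g$first + 1L):(g$last - 1L)] else NULL
      calls[[length(calls) + 1L]] <- data.frame(
        type = g$type, chrom = ch, start = start, end = end,
        size = end - start + 1,
        normRD = mean(bins, na.rm = TRUE) / stats$m,
        e_val1 = region_t_pvalue(bins, stats$m, stats),
        e_val2 = region_tail_pvalue(bins, stats, stats$n_bins_genome),
        e_val3 = if (is.null(inner)) NA_real_
                 else region_t_pvalue(inner, stats$m, stats),
        e_val4 = if (is.null(inner)) NA_real_
                 else region_tail_pvalue(inner, stats, stats$n_bins_genome),
        q0 = region_q0(q0_100, rd_100, ch, start, end),
        pN = region_pn(assembly, ch, start, end),
        dG = if (is.null(gaps)) NA_real_
             else distance_to_gap(gaps, ch, start, end),
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(calls)) do.call(rbind, calls)
  else data.frame(type = character(), chrom = character(), start = numeric(),
                  end = numeric(), size = numeric(), normRD = numeric(),
                  e_val1 = numeric(), e_val2 = numeric(), e_val3 = numeric(),
                  e_val4 = numeric(), q0 = numeric(), pN = numeric(),
                  dG = numeric(), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  class(res) <- c("cnv_calls", "data.frame")
  res
}
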
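# Call curation: filtering by the five viewer parameters, multi-sample
# merging by strict reciprocal overlap, and offline gene annotation.

#' Filter CNV calls by the five curation parameters
#'
#' Applies, conjunctively, whichever of the five thresholds are given:
#' size range, maximum e-val1, maximum q0, maximum pN, minimum dG. The
#' call order is preserved; per-reason removal counts are attached as
#' attribute `removed`.
#'
#' @param calls a `cnv_calls` data.frame.
#' @param size_range numeric length-2 `[min, max]` in bp, or NULL.
#' @param e_val1_max,q0_max,pN_max maxima (inclusive), or NULL.
#' @param dG_min minimum distance to gap (inclusive), or NULL.
#' @return filtered calls; idempotent.
#' @export
filter_calls <- function(calls, size_range = NULL, e_val1_max = NULL,
                         q0_max = NULL, pN_max = NULL, dG_min = NULL) {
  keep <- rep(TRUE, nrow(calls))
  removed <- c(size = 0L, e_val1 = 0L, q0 = 0L, pN = 0L, dG = 0L)
  drop_by <- function(cond, reason) {
    cond <- !is.na(cond) & cond
    removed[reason] <<- sum(keep & cond)
    keep <<- keep & !cond
  }
  if (!is.null(size_range))
    drop_by(calls$size < size_range[1] | calls$size > size_range[2], "size")
  if (!is.null(e_val1_max)) drop_by(calls$e_val1 > e_val1_max, "e_val1")
  if (!is.null(q0_max)) drop_by(calls$q0 > q0_max, "q0")
  if (!is.null(pN_max)) drop_by(calls$pN > pN_max, "pN")
  if (!is.null(dG_min)) drop_by(calls$dG < dG_min, "dG")
  out <- calls[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- removed
  class(out) <- class(calls)
  out
}

reciprocal_overlap <- function(s1, e1, s2, e2) {
  ov <- max(0, min(e1, e2) - max(s1, s2) + 1)
  c(ov / (e1 - s1 + 1), ov / (e2 - s2 + 1))
}

#' Merge CNV calls across samples
#'
#' Builds a joint call set: (1) filter each sample's calls with
#' [filter_calls()] settings; (2) sort all calls by chromosome (assembly
#' order), start, end, sample; (3) take the first unprocessed call and
#' gather calls from other samples with strict reciprocal overlap > 50%
#' (both overlap fractions must exceed the threshold); (4) genotype every
#' contributing sample in the intersection region when genotyping contexts
#' are supplied. Members of a group are marked processed and the scan
#' continues linearly. If two calls from one sample match the seed call,
#' the one with larger overlap is kept with a warning.
#'
#' @param call_sets named list of `cnv_calls`, one per sample.
#' @param contexts optional named list (same names) of per-sample
#'   genotyping contexts: each a list with `rd`, `assembly` and optionally
#'   `stats`, `q0_100`, `rd_100`, `baf` as for [genotype_region()].
#' @param chrom_order chromosome ordering for the sort (default: order of
#'   first appearance across samples).
#' @param min_reciprocal overlap threshold (strict; default 0.5).
#' @param ... filter settings passed to [filter_calls()].
#' @return list of `merged_call`s: `chrom`, `start`, `end` (intersection),
#'   `samples`, `calls` (contributing rows), `genotypes` (per-sample
#'   `genotype_result` or NULL).
#' @export
merge_calls <- function(call_sets, contexts = NULL, chrom_order = NULL,
                        min_reciprocal = 0.5, ...) {
  stopifnot(is.list(call_sets), !is.null(names(call_sets)))
  pooled <- do.call(rbind, lapply(names(call_sets), function(sm) {
    cs <- filter_calls(call_sets[[sm]], ...)
    if (nrow(cs) == 0L) return(NULL)
    cs$sample <- sm
    as.data.frame(cs)
  }))
  if (is.null(pooled) || nrow(pooled) == 0L) return(list())
  if (is.null(chrom_order)) chrom_order <- unique(pooled$chrom)
  pooled <- pooled[order(match(pooled$chrom, chrom_order), pooled$start,
                         pooled$end, pooled$sample), , drop = FALSE]
  rownames(pooled) <- NULL
  processed <- rep(FALSE, nrow(pooled))
  merged <- list()
  for (i in seq_len(nrow(pooled))) {
    if (processed[i]) next
    seed <- pooled[i, ]
    members <- i
    for (sm in setdiff(names(call_sets), seed$sample)) {
      cand <- which(!processed & pooled$sample == sm &
                      pooled$chrom == seed$chrom)
      if (length(cand) == 0L) next
      fr <- vapply(cand, function(j) {
        min(reciprocal_overlap(seed$start, seed$end,
                               pooled$start[j], pooled$end[j]))
      }, numeric(1))
      hit <- cand[fr > min_reciprocal]
      if (length(hit) > 1L) {
        warning("sample ", sm, ": multiple calls overlap the seed call; ",
                "keeping the larger overlap")
        hit <- hit[which.max(fr[fr > min_reciprocal])]
      }
      members <- c(members, hit)
    }
    processed[members] <- TRUE
    int_start <- max(pooled$start[members])
    int_end <- min(pooled$end[members])
    genotypes <- NULL
    if (!is.null(contexts)) {
      region <- list(chrom = seed$chrom, start = int_start, end = int_end)
      genotypes <- lapply(pooled$sample[members], function(sm) {
        ctx <- contexts[[sm]]
        if (is.null(ctx)) return(NULL)
        do.call(genotype_region, c(list(region = region), ctx))
      })
      names(genotypes) <- pooled$sample[members]
    }
    merged[[length(merged) + 1L]] <- structure(list(
      chrom = seed$chrom, start = int_start, end = int_end,
      samples = pooled$sample[members],
      calls = pooled[members, , drop = FALSE],
      genotypes = genotypes), class = "merged_call")
  }
  merged
}

#' Annotate calls with overlapping genes from an offline table
#'
#' Tags every overlapping gene with its position relative to the call:
#' `inside` (gene within the call), `covering` (gene spans the whole
#' call), `intersects-left-breakpoint` or `intersects-right-breakpoint`
#' (gene crosses only one call boundary).
#'
#' @param calls a `cnv_calls` data.frame.
#' @param gene_table data.frame with columns name, id, chrom, start, end
#'   (1-based inclusive), or a path to such a TSV.
#' @return calls with an `annotation` column ("name|id|tag", comma
#'   separated; "" when nothing overlaps).
#' @export
annotate_calls <- function(calls, gene_table) {
  if (is.character(gene_table)) {
    if (!file.exists(gene_table)) {
      message("gene table not found; annotation skipped")
      return(calls)
    }
    gene_table <- read.table(gene_table, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
  }
  ann <- character(nrow(calls))
  for (i in seq_len(nrow(calls))) {
    cs <- calls$start[i]; ce <- calls$end[i]
    g <- gene_table[gene_table$chrom == calls$chrom[i] &
                      gene_table$start <= ce & gene_table$end >= cs, ,
                    drop = FALSE]
    if (nrow(g) == 0L) { ann[i] <- ""; next }
    tag <- character(nrow(g))
    for (j in seq_len(nrow(g))) {
      gs <- g$start[j]; ge <- g$end[j]
      tag[j] <- if (gs >= cs && ge <= ce) "inside"
      else if (gs <= cs && ge >= ce) "covering"
      else if (gs < cs) "intersects-left-breakpoint"
      else "intersects-right-breakpoint"
    }
    ann[i] <- paste(sprintf("%s|%s|%s", g$name, g$id, tag), collapse = ",")
  }
  calls$annotation <- ann
  calls
}
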
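# Binned signal container. All genomic signals (read counts, corrected RD,
# q0-read counts, GC%) live in one structure: a bin size that is a multiple
# of the 100-bp base resolution, plus one numeric array per chromosome.
# Bin b (1-based) covers 1-based bases [(b-1)*s + 1, b*s]; the final bin of
# a chromosome may be partial.

#' Construct a binned track
#'
#' @param bin_size bin width in bp; must be a positive multiple of 100.
#' @param values named list of numeric vectors, one per chromosome.
#' @param lengths named numeric vector of chromosome lengths in bp
#'   (optional; enables partial-bin accounting). Array lengths must equal
#'   `ceiling(length / bin_size)` when given.
#' @return a `binned_track`.
#' @export
binned_track <- function(bin_size, values, lengths = NULL) {
  bin_size <- as.integer(bin_size)
  if (bin_size <= 0L || bin_size %% RESOURCE_BIN != 0L)
    stop("bin size must be a positive multiple of ", RESOURCE_BIN, " bp")
  stopifnot(is.list(values), !is.null(names(values)))
  if (!is.null(lengths)) {
    for (ch in names(values)) {
      expected <- as.integer(ceiling(lengths[[ch]] / bin_size))
      if (length(values[[ch]]) != expected)
        stop("chromosome ", ch, ": expected ", expected, " bins, got ",
             length(values[[ch]]))
    }
  }
  structure(list(bin_size = bin_size, values = values, lengths = lengths),
            class = "binned_track")
}

#' @export
print.binned_track <- function(x, ...) {
  cat(sprintf("binned_track: bin size %d bp, %d chromosome(s), %d bins\n",
              x$bin_size, length(x$values),
              sum(lengths(x$values))))
  invisible(x)
}

#' Rebin a track to a coarser resolution
#'
#' Output bins sum their constituent bins, so per-chromosome totals are
#' conserved exactly. Rebinning is restricted to multiples of the input
#' bin size (the base store holds 100-bp bins, so any stored signal can be
#' rebinned to any multiple of 100 bp). The last output bin may sum fewer
#' input bins.
#'
#' @param track a `binned_track`.
#' @param bin_size target bin size; positive multiple of `track$bin_size`.
#' @param fun aggregation over constituent bins: "sum" (counts; default) or
#'   "mean" (intensive signals such as GC% or mean depth; NA constituents
#'   are dropped from the mean).
#' @return a `binned_track` at the new bin size.
#' @export
rebin <- function(track, bin_size, fun = c("sum", "mean")) {
  fun <- match.arg(fun)
  bin_size <- as.integer(bin_size)
  if (bin_size <= 0L || bin_size %% track$bin_size != 0L)
    stop("bin size must be a positive multiple of the stored ",
         track$bin_size, "-bp bins")
  k <- bin_size %/% track$bin_size
  vals <- lapply(track$values, function(v) {
    nb <- ceiling(length(v) / k)
    grp <- rep(seq_len(nb), each = k, length.out = length(v))
    if (fun == "sum") {
      as.numeric(tapply(v, grp, sum))
    } else {
      as.numeric(tapply(v, grp, function(z) {
        z <- z[!is.na(z)]
        if (length(z) == 0L) NA_real_ else mean(z)
      }))
    }
  })
  binned_track(bin_size, vals, track$lengths)
}

#' Integer GC percentage per bin
#'
#' Pools the 100-bp GC and AT base counts inside each bin and reports
#' round(100 * GC / (GC + AT)) — a pooled recomputation, not a mean of
#' per-100-bp percentages. Bins with no usable (non-N, non-ambiguous)
#' bases get NA and are treated as unusable downstream.
#'
#' @param assembly a `genome_assembly`.
#' @param bin_size bin size, multiple of 100.
#' @return a `binned_track` of integer GC% with NA for unusable bins.
#' @export
gc_per_bin <- function(assembly, bin_size) {
  gc <- binned_track(RESOURCE_BIN, assembly$gc_100, assembly$lengths)
  at <- binned_track(RESOURCE_BIN, assembly$at_100, assembly$lengths)
  if (bin_size != RESOURCE_BIN) {
    gc <- rebin(gc, bin_size)
    at <- rebin(at, bin_size)
  }
  vals <- lapply(assembly$chroms, function(ch) {
    g <- gc$values[[ch]]; a <- at$values[[ch]]
    tot <- g + a
    out <- ifelse(tot > 0, round(100 * g / pmax(tot, 1)), NA_real_)
    as.numeric(out)
  })
  names(vals) <- assembly$chroms
  binned_track(bin_size, vals, assembly$lengths)
}

#' N-base fraction per bin
#'
#' @inheritParams gc_per_bin
#' @return a `binned_track` of fractions in `[0, 1]`.
#' @export
n_fraction_per_bin <- function(assembly, bin_size) {
  nn <- binned_track(RESOURCE_BIN, assembly$n_100, assembly$lengths)
  if (bin_size != RESOURCE_BIN) nn <- rebin(nn, bin_size)
  vals <- lapply(assembly$chroms, function(ch) {
    len <- assembly$lengths[[ch]]
    nb <- length(nn$values[[ch]])
    span <- rep(bin_size, nb)
    if (len %% bin_size != 0) span[nb] <- len %% bin_size
    nn$values[[ch]] / span
  })
  names(vals) <- assembly$chroms
  binned_track(bin_size, vals, assembly$lengths)
}

# Fraction of each bin of `track` covered by the chromosome (last bin of a
# chromosome may be partial). Used to down-weight terminal bins.
bin_coverage_fraction <- function(track, chrom) {
  v <- track$values[[chrom]]
  frac <- rep(1, length(v))
  if (!is.null(track$lengths)) {
    len <- track$lengths[[chrom]]
    rem <- len %% track$bin_size
    if (rem != 0) frac[length(v)] <- rem / track$bin_size
  }
  frac
}
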
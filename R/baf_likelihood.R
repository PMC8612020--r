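# Per-bin BAF likelihood. Unphased counts mean a het's alternative allele
# sits on either haplotype with equal chance, so the allele-fraction
# likelihood of one site is the symmetrized beta kernel
#
#   L(p | alt, ref)  ~  p^alt (1-p)^ref + p^ref (1-p)^alt ,
#
# and the bin likelihood is the product over in-mask het sites in the bin,
# evaluated on a discrete grid over [0, 0.5] (the symmetry makes [0.5, 1]
# redundant) and max-normalized. The grid location of the maximum is the
# most probable BAF of the bin: 0.5 for balanced diploid bins, 1/3 for a
# one-haplotype duplication, intermediate for subclonal events.

#' Discretization grid for BAF likelihoods
#' @param points number of grid points spanning `[0, 0.5]` inclusive
#'   (default 101).
#' @return numeric vector of allele fractions.
#' @export
baf_grid <- function(points = 101L) seq(0, 0.5, length.out = points)

#' Log-likelihood of one het site on a grid
#'
#' Evaluates the symmetrized beta kernel in log space (stable for deep
#' coverage). Any positive scaling is permitted: normalization happens at
#' bin level.
#'
#' @param alt,ref allele read counts of the site.
#' @param grid allele-fraction grid (see [baf_grid()]).
#' @return numeric vector of log-likelihood values (may contain -Inf at
#'   the grid endpoints).
#' @export
site_log_likelihood <- function(alt, ref, grid) {
  lp <- log(grid)
  l1p <- log1p(-grid)
  term <- function(a, b) {
    t <- numeric(length(grid))
    if (a != 0) t <- t + a * lp
    if (b != 0) t <- t + b * l1p
    t
  }
  logsumexp2(term(alt, ref), term(ref, alt))
}

#' @rdname site_log_likelihood
#' @export
site_likelihood <- function(alt, ref, grid) {
  ll <- site_log_likelihood(alt, ref, grid)
  exp(ll - max(ll))
}

# argmax with ties broken toward larger p (closer to the 0.5 null)
grid_argmax <- function(values) {
  length(values) + 1L - which.max(rev(values))
}

#' Per-bin BAF likelihood functions
#'
#' Multiplies the symmetrized-beta likelihoods of all in-mask heterozygous
#' sites in each bin (log-space accumulation), max-normalizes each bin's
#' grid, and records the most probable BAF together with per-bin het/hom
#' counts and mean BAF/MAF. Bins with no usable het are flagged empty.
#'
#' @param sites mask-filtered `variant_sites`.
#' @param bin_size bin size in bp (multiple of 100).
#' @param assembly `genome_assembly` (chromosome sizes).
#' @param grid_points grid resolution over `[0, 0.5]` (default 101).
#' @return a `bin_likelihood` object: per-chromosome likelihood matrices
#'   (bins x grid, NA rows for empty bins), `ml_baf`, `n_het`, `n_hom`,
#'   `mean_baf`, `mean_maf`.
#' @export
bin_likelihood <- function(sites, bin_size, assembly, grid_points = 101L) {
  bin_size <- as.integer(bin_size)
  if (bin_size %% RESOURCE_BIN != 0L)
    stop("bin size must be a multiple of ", RESOURCE_BIN, " bp")
  grid <- baf_grid(grid_points)
  res <- list(bin_size = bin_size, grid = grid, lik = list(), ml_baf = list(),
              n_het = list(), n_hom = list(), mean_baf = list(),
              mean_maf = list())
  for (ch in assembly$chroms) {
    nb <- as.integer(ceiling(assembly$lengths[[ch]] / bin_size))
    lik <- matrix(NA_real_, nrow = nb, ncol = grid_points)
    ml <- rep(NA_real_, nb)
    nhet <- nhom <- integer(nb)
    mbaf <- mmaf <- rep(NA_real_, nb)
    s <- sites[sites$chrom == ch, , drop = FALSE]
    if (nrow(s)) {
      b <- pos_to_bin(s$pos, bin_size)
      inb <- b >= 1L & b <= nb
      s <- s[inb, , drop = FALSE]; b <- b[inb]
      nhet <- tabulate(b[s$gt == "het"], nbins = nb)
      nhom <- tabulate(b[s$gt == "hom"], nbins = nb)
      bvals <- baf(s)
      for (bin in unique(b)) {
        in_bin <- b == bin
        mbaf[bin] <- mean(bvals[in_bin], na.rm = TRUE)
        mmaf[bin] <- mean(pmin(bvals[in_bin], 1 - bvals[in_bin]), na.rm = TRUE)
        use <- in_bin & s$gt == "het" & s$in_mask %in% TRUE &
          (s$ref_count + s$alt_count) > 0
        if (!any(use)) next
        ll <- numeric(grid_points)
        for (i in which(use))
          ll <- ll + site_log_likelihood(s$alt_count[i], s$ref_count[i], grid)
        lik[bin, ] <- exp(ll - max(ll))
        ml[bin] <- grid[grid_argmax(lik[bin, ])]
      }
    }
    res$lik[[ch]] <- lik
    res$ml_baf[[ch]] <- ml
    res$n_het[[ch]] <- nhet
    res$n_hom[[ch]] <- nhom
    res$mean_baf[[ch]] <- mbaf
    res$mean_maf[[ch]] <- mmaf
  }
  structure(res, class = "bin_likelihood")
}

#' @export
print.bin_likelihood <- function(x, ...) {
  nb <- sum(vapply(x$ml_baf, length, 0L))
  ne <- sum(vapply(x$ml_baf, function(v) sum(!is.na(v)), 0L))
  cat(sprintf("bin_likelihood: bin size %d bp, %d bins (%d with BAF data), %d-point grid\n",
              x$bin_size, nb, ne, length(x$grid)))
  invisible(x)
}

#' Read-depth proxy from variant coverage
#'
#' When no alignment file is available, the mean DP of variants in a bin
#' tracks the true coverage well at large (>= 10 kb) bins and can feed the
#' downstream depth pipeline. Variant-free bins are flagged missing (NA),
#' not zero; at coarser rebinning missing constituents are simply dropped
#' from the mean.
#'
#' @param sites `variant_sites` with DP (or ref+alt fallback).
#' @param bin_size bin size in bp.
#' @param assembly `genome_assembly`.
#' @return a `binned_track` of mean per-variant depth (NA = no variants).
#' @export
rd_from_variant_depth <- function(sites, bin_size, assembly) {
  depth <- ifelse(is.na(sites$dp), sites$ref_count + sites$alt_count,
                  sites$dp)
  if (!any(!is.na(depth) & depth > 0))
    stop("no variant sites carry depth information")
  vals <- list()
  for (ch in assembly$chroms) {
    nb <- as.integer(ceiling(assembly$lengths[[ch]] / bin_size))
    v <- rep(NA_real_, nb)
    sel <- sites$chrom == ch & !is.na(depth)
    if (any(sel)) {
      b <- pos_to_bin(sites$pos[sel], bin_size)
      ok <- b >= 1L & b <= nb
      agg <- tapply(depth[sel][ok], b[ok], mean)
      v[as.integer(names(agg))] <- as.numeric(agg)
    }
    vals[[ch]] <- v
  }
  binned_track(as.integer(bin_size), vals, assembly$lengths)
}
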
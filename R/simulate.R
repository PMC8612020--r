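# Synthetic fixture generation. Everything the pipeline consumes — a
# reference with controllable GC structure and gaps, coordinate-sorted
# alignments with planted copy-number events and GC bias, and VCFs whose
# het allele fractions follow the copy-state mixture — can be produced
# offline, deterministically per seed, with the planted truth returned
# alongside. Defaults emulate a 30x short-read WGS experiment: Poisson
# read placement, 100-bp reads, ~1 het per kb.
#
# Planted events carry per-haplotype copy numbers (h1, h2) and a cell
# fraction: a one-haplotype deletion is (1, 0), a one-haplotype
# duplication (2, 1), CNN-LOH (2, 0). At cell fraction cf the effective
# copies mix with the diploid background, so a het's alt-allele fraction
# is (cf*h_alt + (1-cf)) / (cf*(h1+h2) + 2*(1-cf)): 1/2 for diploid, 2/3
# or 1/3 inside a full duplication depending on which haplotype carries
# the alt allele, and 0 or 1 inside deletions and CNN-LOH (so those
# regions emit no hets, only homs).

event_copies <- function(type) {
  switch(type,
         deletion = c(1, 0),
         duplication = c(2, 1),
         cnn_loh = c(2, 0),
         stop("unknown event type: ", type))
}

#' Build a truth-event table
#'
#' @param type event types ("deletion", "duplication", "cnn_loh").
#' @param chrom,start,end event regions (1-based inclusive).
#' @param h1,h2 copies per haplotype; defaults from the type.
#' @param cell_fraction fraction of cells carrying the event (default 1).
#' @return data.frame of truth events.
#' @export
truth_events <- function(type, chrom, start, end, h1 = NULL, h2 = NULL,
                         cell_fraction = 1) {
  n <- length(type)
  if (is.null(h1)) {
    cp <- vapply(type, event_copies, numeric(2))
    h1 <- cp[1, ]; h2 <- cp[2, ]
  }
  data.frame(type = type, chrom = chrom, start = start, end = end,
             h1 = h1, h2 = h2,
             cell_fraction = rep(cell_fraction, length.out = n),
             stringsAsFactors = FALSE)
}

# Per-base total copy factor (relative to diploid) along one chromosome.
copy_factor_100 <- function(chrom, n_bins, events) {
  cf <- rep(1, n_bins)
  if (is.null(events)) return(cf)
  ev <- events[events$chrom == chrom, , drop = FALSE]
  for (i in seq_len(nrow(ev))) {
    b1 <- max(1L, pos_to_bin(ev$start[i], RESOURCE_BIN))
    b2 <- min(n_bins, pos_to_bin(ev$end[i], RESOURCE_BIN))
    total <- ev$cell_fraction[i] * (ev$h1[i] + ev$h2[i]) +
      (1 - ev$cell_fraction[i]) * 2
    cf[b1:b2] <- total / 2
  }
  cf
}

#' Simulate a reference genome
#'
#' Per-100-bp GC content follows the requested profile; gaps are planted
#' as N runs. Deterministic per seed.
#'
#' @param lengths named numeric vector of chromosome lengths (>= 10 kb).
#' @param gc_profile list describing the GC landscape: `type` one of
#'   "flat" (`gc` fraction), "block" (`levels`, `block_bins`), "sine"
#'   (`mean`, `amplitude`, `period_bins`).
#' @param gaps optional data.frame chrom/start/end (1-based inclusive) of
#'   N runs to plant.
#' @param seed RNG seed.
#' @param fasta optional path; when given, the sequences are written as
#'   FASTA.
#' @return list: `sequences` (DNAStringSet), `assembly`
#'   (`genome_assembly`), `gaps` (`gap_set`).
#' @export
simulate_reference <- function(lengths,
                               gc_profile = list(type = "flat", gc = 0.45),
                               gaps = NULL, seed = 1, fasta = NULL) {
  stopifnot(!is.null(names(lengths)), all(lengths >= 1e4))
  set.seed(seed)
  seqs <- lapply(names(lengths), function(ch) {
    len <- lengths[[ch]]
    nb <- ceiling(len / RESOURCE_BIN)
    g <- switch(gc_profile$type,
      flat = rep(gc_profile$gc, nb),
      block = gc_profile$levels[
        ((seq_len(nb) - 1L) %/% gc_profile$block_bins) %%
          length(gc_profile$levels) + 1L],
      sine = gc_profile$mean + gc_profile$amplitude *
        sin(2 * pi * seq_len(nb) / gc_profile$period_bins),
      stop("unknown gc profile type"))
    # exact composition per 100-bp bin (round(g * width) GC bases at
    # random positions), so the realized GC track matches the requested
    # profile to rounding rather than to binomial noise
    base <- character(len)
    for (b in seq_len(nb)) {
      lo <- (b - 1L) * RESOURCE_BIN + 1L
      width <- min(RESOURCE_BIN, len - lo + 1L)
      k <- round(g[b] * width)
      bb <- c(sample(c("G", "C"), k, replace = TRUE),
              sample(c("A", "T"), width - k, replace = TRUE))
      base[lo:(lo + width - 1L)] <- bb[sample.int(width)]
    }
    if (!is.null(gaps)) {
      gv <- gaps[gaps$chrom == ch, , drop = FALSE]
      for (i in seq_len(nrow(gv)))
        base[gv$start[i]:min(gv$end[i], len)] <- "N"
    }
    paste(base, collapse = "")
  })
  names(seqs) <- names(lengths)
  dss <- Biostrings::DNAStringSet(unlist(seqs))
  if (!is.null(fasta)) Biostrings::writeXStringSet(dss, fasta)
  list(sequences = dss, assembly = compute_content(dss),
       gaps = find_gaps(dss))
}

#' Simulate a coordinate-sorted SAM file with planted events
#'
#' Read starts are Poisson-placed per 100-bp bin with rate
#' coverage * 100 / read_length, scaled by the local copy factor of any
#' overlapping event (cell-fraction mixture) and by the supplied GC-bias
#' multiplier for the bin's GC class. A stated fraction of reads carries
#' mapping quality 0. Reads are emitted pre-aligned: positions are known
#' by construction, no aligner runs.
#'
#' @param assembly `genome_assembly` of the simulated reference.
#' @param path output SAM path.
#' @param coverage haploid-pair (diploid) coverage, e.g. 30.
#' @param read_length read length in bp.
#' @param events optional truth-event data.frame (see [truth_events()]).
#' @param gc_bias optional function(gc_percent) -> rate multiplier.
#' @param q0_fraction fraction of reads emitted with mapping quality 0.
#' @param seed RNG seed.
#' @return the SAM path, invisibly; attribute `truth` carries the events.
#' @export
simulate_alignments <- function(assembly, path, coverage = 30,
                                read_length = 100L, events = NULL,
                                gc_bias = NULL, q0_fraction = 0,
                                seed = 1) {
  stopifnot(coverage > 0)
  if (!is.null(events)) {
    for (i in seq_len(nrow(events))) {
      ch <- events$chrom[i]
      if (!ch %in% assembly$chroms ||
          events$end[i] > assembly$lengths[[ch]])
        stop("event outside reference: ", ch, ":", events$start[i], "-",
             events$end[i])
    }
  }
  set.seed(seed)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:coordinate",
               sprintf("@SQ\tSN:%s\tLN:%d", assembly$chroms,
                       as.integer(assembly$lengths))), con)
  base_rate <- coverage * RESOURCE_BIN / read_length
  rid <- 0L
  for (ch in assembly$chroms) {
    len <- assembly$lengths[[ch]]
    nb <- length(assembly$gc_100[[ch]])
    rate <- rep(base_rate, nb) * copy_factor_100(ch, nb, events)
    if (!is.null(gc_bias)) {
      gcat <- assembly$gc_100[[ch]] + assembly$at_100[[ch]]
      gcp <- ifelse(gcat > 0,
                    round(100 * assembly$gc_100[[ch]] / pmax(gcat, 1)), NA)
      mult <- ifelse(is.na(gcp), 0, gc_bias(gcp))
      rate <- rate * mult
    }
    # no reads start where they cannot fit, or inside all-N bins
    rate[assembly$n_100[[ch]] == RESOURCE_BIN] <- 0
    last_start_bin <- pos_to_bin(max(1, len - read_length + 1), RESOURCE_BIN)
    if (last_start_bin < nb) rate[(last_start_bin + 1L):nb] <- 0
    counts <- rpois(nb, rate)
    tot <- sum(counts)
    if (tot == 0L) next
    binidx <- rep.int(seq_len(nb), counts)
    offs <- sample.int(RESOURCE_BIN, tot, replace = TRUE) - 1L
    pos <- pmin((binidx - 1L) * RESOURCE_BIN + 1L + offs,
                len - read_length + 1)
    pos <- sort(pos)
    mapq <- ifelse(runif(tot) < q0_fraction, 0L, 60L)
    lines <- sprintf("r%08d\t0\t%s\t%d\t%d\t%dM\t*\t0\t0\t*\t*",
                     rid + seq_len(tot), ch, pos, mapq, read_length)
    rid <- rid + tot
    writeLines(lines, con)
  }
  attr(path, "truth") <- events
  invisible(path)
}

#' Simulate a VCF of SNVs with copy-state-driven allele fractions
#'
#' Het sites are placed at `het_density` per bp inside strict-mask P
#' regions (everywhere, if no mask is given), each assigned to one of the
#' two haplotypes at random; the alt count is binomial(depth_i, f) with f
#' the alt-haplotype copy fraction implied by any overlapping event and
#' its cell fraction. Sites whose f collapses to 0 are not emitted (the
#' variant would not be discovered); f = 1 sites are emitted as hom 1/1 —
#' deletion and CNN-LOH regions therefore show homs but no hets. Hom
#' sites (f = 1) are additionally placed at `hom_density`. An
#' `outlier_fraction` of extra sites is placed outside the mask with
#' corrupted allele fractions, mimicking systematic misalignment noise.
#'
#' @param assembly `genome_assembly`.
#' @param path output VCF path.
#' @param het_density,hom_density sites per bp (defaults 1e-3, 6.6e-4).
#' @param depth mean per-site depth; site depths are Poisson(depth).
#' @param events optional truth-event data.frame.
#' @param mask optional `strict_mask` of P regions.
#' @param outlier_fraction fraction of het-site count added as corrupted
#'   off-mask sites.
#' @param seed RNG seed.
#' @return the VCF path, invisibly; attribute `sites` is the truth table
#'   of emitted records.
#' @export
simulate_vcf <- function(assembly, path, het_density = 1e-3,
                         hom_density = 6.6e-4, depth = 30, events = NULL,
                         mask = NULL, outlier_fraction = 0, seed = 1) {
  stopifnot(het_density > 0)
  set.seed(seed)
  rows <- list()
  for (ch in assembly$chroms) {
    len <- assembly$lengths[[ch]]
    n_het <- rpois(1, len * het_density)
    n_hom <- rpois(1, len * hom_density)
    pos <- sort(sample.int(len, min(len, n_het + n_hom)))
    is_het <- rep(FALSE, length(pos))
    if (length(pos))
      is_het[sample.int(length(pos), min(n_het, length(pos)))] <- TRUE
    if (!is.null(mask)) {
      inm <- in_strict_mask(mask, ch, pos)
      pos <- pos[inm]; is_het <- is_het[inm]
    }
    f <- ifelse(is_het, 0.5, 1)
    dfac <- rep(1, length(pos))  # depth scales with total copy state
    hap <- sample.int(2L, length(pos), replace = TRUE)
    if (!is.null(events)) {
      ev <- events[events$chrom == ch, , drop = FALSE]
      for (i in seq_len(nrow(ev))) {
        sel <- pos >= ev$start[i] & pos <= ev$end[i]
        if (!any(sel)) next
        cf <- ev$cell_fraction[i]
        tot <- cf * (ev$h1[i] + ev$h2[i]) + 2 * (1 - cf)
        h_alt <- ifelse(hap[sel] == 1L, ev$h1[i], ev$h2[i])
        f[sel] <- ifelse(is_het[sel],
                         (cf * h_alt + (1 - cf)) / tot, 1)
        dfac[sel] <- tot / 2
      }
    }
    n_out <- rpois(1, sum(is_het) * outlier_fraction)
    if (n_out > 0 && !is.null(mask)) {
      cand <- sample.int(len, min(len, 20L * n_out))
      cand <- cand[!in_strict_mask(mask, ch, cand)]
      cand <- utils::head(cand, n_out)
      pos <- c(pos, cand); is_het <- c(is_het, rep(TRUE, length(cand)))
      f <- c(f, stats::rbeta(length(cand), 0.2, 0.2))
      dfac <- c(dfac, rep(1, length(cand)))
      ord <- order(pos)
      pos <- pos[ord]; is_het <- is_het[ord]; f <- f[ord]
      dfac <- dfac[ord]
    }
    keep <- f > 0
    pos <- pos[keep]; is_het <- is_het[keep]; f <- f[keep]
    dfac <- dfac[keep]
    if (length(pos) == 0L) next
    d <- pmax(1L, rpois(length(pos), depth * dfac))
    alt <- rbinom(length(pos), d, f)
    gt <- ifelse(is_het & f < 1, "0/1", "1/1")
    rows[[ch]] <- data.frame(
      chrom = ch, pos = pos, ref = "A", alt_base = "G",
      ref_count = d - alt, alt_count = alt, dp = d, gt = gt,
      true_f = f, stringsAsFactors = FALSE)
  }
  sites <- do.call(rbind, rows)
  hdr <- c("##fileformat=VCFv4.2",
           "##source=rdcnv-simulator",
           sprintf("##contig=<ID=%s,length=%d>", assembly$chroms,
                   as.integer(assembly$lengths)),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tSAMPLE")
  body <- if (is.null(sites)) character(0) else
    sprintf("%s\t%d\t.\t%s\t%s\t100\tPASS\t.\tGT:AD:DP\t%s:%d,%d:%d",
            sites$chrom, sites$pos, sites$ref, sites$alt_base, sites$gt,
            sites$ref_count, sites$alt_count, sites$dp)
  writeLines(c(hdr, body), path)
  attr(path, "sites") <- sites
  invisible(path)
}

#' Simulate a binned read-depth track directly
#'
#' Shortcut generator for scale tests that do not need an alignment file:
#' per-100-bp Poisson counts at `coverage * 100 / read_length` reads per
#' bin, scaled by planted events, on a uniform-GC diploid chromosome.
#'
#' @param n_bins number of bins of size `bin_size` on one chromosome.
#' @param bin_size target bin size (multiple of 100).
#' @param coverage diploid coverage (default 30).
#' @param read_length read length used for the rate (default 100).
#' @param events optional data.frame with first_bin/last_bin (at
#'   `bin_size` resolution) and `factor` (copy factor, e.g. 0.5, 1.5).
#' @param seed RNG seed.
#' @return list: `rd_100` (100-bp `binned_track`), `rd` (rebinned to
#'   `bin_size`), `assembly` (uniform-GC stand-in).
#' @export
simulate_binned_rd <- function(n_bins, bin_size, coverage = 30,
                               read_length = 100L, events = NULL,
                               seed = 1) {
  set.seed(seed)
  bin_size <- as.integer(bin_size)
  k <- bin_size %/% RESOURCE_BIN
  n100 <- n_bins * k
  rate <- rep(coverage * RESOURCE_BIN / read_length, n100)
  if (!is.null(events)) {
    for (i in seq_len(nrow(events))) {
      b1 <- (events$first_bin[i] - 1L) * k + 1L
      b2 <- events$last_bin[i] * k
      rate[b1:b2] <- rate[b1:b2] * events$factor[i]
    }
  }
  counts <- rpois(n100, rate)
  len <- n100 * RESOURCE_BIN
  assembly <- synthetic_assembly(c(sim = len))
  rd_100 <- binned_track(RESOURCE_BIN, list(sim = as.numeric(counts)),
                         assembly$lengths)
  list(rd_100 = rd_100, rd = rebin(rd_100, bin_size), assembly = assembly)
}

#' Uniform-GC stand-in assembly
#'
#' A `genome_assembly` with constant 50% GC and no N bases, for tests and
#' simulations that need chromosome geometry but no real sequence.
#'
#' @param lengths named numeric vector of chromosome lengths.
#' @return a `genome_assembly`.
#' @export
synthetic_assembly <- function(lengths) {
  gc <- at <- nn <- list()
  for (ch in names(lengths)) {
    len <- lengths[[ch]]
    nb <- as.integer(ceiling(len / RESOURCE_BIN))
    full <- rep(50L, nb)
    rem <- len %% RESOURCE_BIN
    if (rem != 0) full[nb] <- as.integer(rem %/% 2L)
    gc[[ch]] <- full
    at[[ch]] <- if (rem != 0) c(full[-nb], as.integer(rem - rem %/% 2L))
                else full
    nn[[ch]] <- rep(0L, nb)
  }
  structure(list(chroms = names(lengths),
                 lengths = setNames(as.numeric(lengths), names(lengths)),
                 gc_100 = gc, at_100 = at, n_100 = nn,
                 autosome = setNames(rep(TRUE, length(lengths)),
                                     names(lengths))),
            class = "genome_assembly")
}
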
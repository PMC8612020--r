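# Genome resources: per-100-bp base composition, strict accessibility mask,
# and assembly-gap geometry. These back GC correction, the pN statistic and
# the dG (distance-to-gap) statistic of CNV calls.

RESOURCE_BIN <- 100L

#' Compute per-100-bp base composition for an assembly
#'
#' Tabulates GC, AT and N counts in consecutive 100-bp bins of each
#' chromosome. This is the only information retained from the reference:
#' downstream GC correction, pN and gap geometry all work from these counts,
#' so the FASTA is not needed again after this step.
#'
#' Lowercase (soft-masked) bases are counted like their uppercase versions.
#' IUPAC ambiguity codes other than N count as neither GC, AT nor N; a full
#' bin therefore satisfies gc + at + n <= 100, with equality for a pure
#' A/C/G/T/N alphabet. The final bin of a chromosome may be partial.
#'
#' @param sequences a named [Biostrings::DNAStringSet] (or named character
#'   vector of sequences), one element per chromosome.
#' @param autosomes optional character vector naming the autosomal
#'   chromosomes. Default: every chromosome whose name (minus any "chr"
#'   prefix) is numeric.
#' @return a `genome_assembly` object: chromosome names and lengths plus
#'   `gc_100`, `at_100`, `n_100` integer count arrays per chromosome.
#' @examples
#' ga <- compute_content(c(seq1 = strrep("ACGT", 50)))
#' ga$gc_100[["seq1"]]
#' @export
compute_content <- function(sequences, autosomes = NULL) {
  if (is.character(sequences)) sequences <- Biostrings::DNAStringSet(sequences)
  nms <- names(sequences)
  if (is.null(nms) || any(nms == ""))
    stop("all chromosomes must be named")
  lens <- Biostrings::width(sequences)
  if (any(lens == 0L))
    stop("empty chromosome: ", paste(nms[lens == 0L], collapse = ", "))
  gc <- at <- nn <- vector("list", length(nms))
  names(gc) <- names(at) <- names(nn) <- nms
  for (i in seq_along(nms)) {
    len <- lens[i]
    nb <- as.integer(ceiling(len / RESOURCE_BIN))
    starts <- seq.int(1L, by = RESOURCE_BIN, length.out = nb)
    ends <- pmin(starts + RESOURCE_BIN - 1L, len)
    v <- Biostrings::Views(sequences[[i]], start = starts, end = ends)
    freq <- Biostrings::letterFrequency(v, letters = c("CG", "AT", "N"))
    gc[[i]] <- as.integer(freq[, "C|G"])
    at[[i]] <- as.integer(freq[, "A|T"])
    nn[[i]] <- as.integer(freq[, "N"])
  }
  if (is.null(autosomes)) {
    autosomes <- nms[grepl("^[0-9]+$", sub("^chr", "", nms))]
    if (length(autosomes) == 0L) autosomes <- nms  # toy assemblies: use all
  }
  structure(list(
    chroms = nms,
    lengths = setNames(as.numeric(lens), nms),
    gc_100 = gc, at_100 = at, n_100 = nn,
    autosome = setNames(nms %in% autosomes, nms)
  ), class = "genome_assembly")
}

#' @export
print.genome_assembly <- function(x, ...) {
  cat(sprintf("genome_assembly: %d chromosome(s), %.0f bp total (%d autosomal)\n",
              length(x$chroms), sum(x$lengths), sum(x$autosome)))
  invisible(x)
}

#' Read a reference FASTA and compute its 100-bp composition
#'
#' @param path FASTA file (plain or bgzipped).
#' @inheritParams compute_content
#' @return a `genome_assembly`.
#' @export
read_reference <- function(path, autosomes = NULL) {
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  compute_content(seqs, autosomes = autosomes)
}

#' Load a strict accessibility mask from BED
#'
#' The mask lists "passed" (P) intervals: regions of the genome where short
#' reads can be aligned reliably enough for variant discovery. Variants
#' outside P regions are filtered before any BAF computation. BED input is
#' 0-based half-open; intervals are sorted and merged on load.
#'
#' @param path BED file of P intervals, or a data.frame with columns
#'   chrom/start/end (0-based half-open).
#' @param known_chroms optional character vector; intervals on chromosomes
#'   outside this set are dropped with a warning count.
#' @return a `strict_mask` object (per-chromosome [IRanges::IRanges], stored
#'   0-based half-open as (start, end] semantics on 1-based positions).
#' @export
load_strict_mask <- function(path, known_chroms = NULL) {
  if (is.data.frame(path)) {
    bed <- path
    names(bed)[1:3] <- c("chrom", "start", "end")
  } else {
    lines <- readLines(path)
    lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
    if (length(lines) == 0L) {
      return(structure(list(intervals = list()), class = "strict_mask"))
    }
    parts <- strsplit(lines, "\t| +")
    nf <- lengths(parts)
    if (any(nf < 3L))
      stop("malformed BED line ", which(nf < 3L)[1], ": fewer than 3 fields")
    chrom <- vapply(parts, `[[`, "", 1L)
    start <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
    end <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 3L)))
    bad <- which(is.na(start) | is.na(end) | end < start)
    if (length(bad))
      stop("malformed BED line ", bad[1], ": non-numeric or inverted interval")
    bed <- data.frame(chrom = chrom, start = start, end = end)
  }
  if (!is.null(known_chroms)) {
    norm <- normalize_chrom(bed$chrom, known_chroms)
    n_skip <- sum(is.na(norm))
    if (n_skip > 0)
      warning(n_skip, " interval(s) on unknown chromosomes skipped")
    bed <- bed[!is.na(norm), , drop = FALSE]
    bed$chrom <- norm[!is.na(norm)]
  }
  iv <- lapply(split(bed, bed$chrom), function(d) {
    # store as 1-based inclusive IRanges internally; BED (s,e] 0-based
    # half-open covers 1-based positions s+1 .. e
    IRanges::reduce(IRanges::IRanges(start = d$start + 1L, end = d$end))
  })
  structure(list(intervals = iv), class = "strict_mask")
}

#' Test 1-based positions for strict-mask membership
#'
#' @param mask a `strict_mask`.
#' @param chrom chromosome name (scalar).
#' @param pos vector of 1-based positions.
#' @return logical vector, TRUE where the position falls in a P interval.
#' @export
in_strict_mask <- function(mask, chrom, pos) {
  iv <- mask$intervals[[chrom]]
  if (is.null(iv)) return(rep(FALSE, length(pos)))
  IRanges::overlapsAny(IRanges::IRanges(pos, pos), iv)
}

#' Serialize a strict mask back to BED
#' @param mask a `strict_mask`.
#' @param path output BED path.
#' @export
write_strict_mask <- function(mask, path) {
  rows <- lapply(names(mask$intervals), function(ch) {
    iv <- mask$intervals[[ch]]
    if (length(iv) == 0L) return(NULL)
    data.frame(chrom = ch, start = IRanges::start(iv) - 1L,
               end = IRanges::end(iv))
  })
  bed <- do.call(rbind, rows)
  if (is.null(bed)) bed <- data.frame(chrom = character(), start = numeric(),
                                      end = numeric())
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Locate assembly gaps (runs of N)
#'
#' Gaps are maximal runs of N in the reference. With raw sequence available
#' they are exact; from a `genome_assembly` alone they are resolved at
#' 100-bp granularity as maximal runs of bins with n = 100.
#'
#' @param x a named DNAStringSet / character vector of sequences, or a
#'   `genome_assembly`.
#' @return a `gap_set`: per-chromosome [IRanges::IRanges] of gaps, 1-based
#'   inclusive internally (exported BED would be 0-based half-open).
#' @export
find_gaps <- function(x) {
  if (inherits(x, "genome_assembly")) {
    gaps <- lapply(x$chroms, function(ch) {
      full <- which(x$n_100[[ch]] == RESOURCE_BIN)
      if (length(full) == 0L) return(IRanges::IRanges())
      r <- IRanges::reduce(IRanges::IRanges(full, full))
      IRanges::IRanges(start = (IRanges::start(r) - 1L) * RESOURCE_BIN + 1L,
                       end = IRanges::end(r) * RESOURCE_BIN)
    })
    names(gaps) <- x$chroms
  } else {
    if (is.character(x)) x <- Biostrings::DNAStringSet(x)
    gaps <- lapply(seq_along(x), function(i) {
      m <- Biostrings::maskMotif(x[[i]], "N")
      as(Biostrings::masks(m)[[1]], "IRanges")
    })
    names(gaps) <- names(x)
  }
  structure(list(gaps = gaps), class = "gap_set")
}

#' Distance from a region to the nearest assembly gap
#'
#' Returns 0 when the region overlaps a gap; otherwise the number of bases
#' strictly between the region and the nearest gap edge. A chromosome with
#' no gaps returns `Inf`.
#'
#' @param gapset a `gap_set`.
#' @param chrom chromosome name.
#' @param start,end region, 1-based inclusive.
#' @return distance in base pairs (0, positive, or Inf).
#' @export
distance_to_gap <- function(gapset, chrom, start, end) {
  if (!chrom %in% names(gapset$gaps))
    stop("unknown chromosome: ", chrom)
  g <- gapset$gaps[[chrom]]
  if (length(g) == 0L) return(Inf)
  gs <- IRanges::start(g); ge <- IRanges::end(g)
  if (any(gs <= end & ge >= start)) return(0)
  # gaps fully to the right / left of the region
  right <- gs[gs > end]; left <- ge[ge < start]
  d <- Inf
  if (length(right)) d <- min(d, min(right) - end - 1)
  if (length(left)) d <- min(d, start - max(left) - 1)
  d
}
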
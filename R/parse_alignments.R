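# Alignment parsing: reduce a coordinate-sorted SAM/BAM/CRAM file to two
# 100-bp binned tracks — total read count and mapping-quality-zero read
# count. Everything downstream (rebinning, GC correction, segmentation,
# calling) works from these tracks alone.

#' Extract 100-bp read-depth and q0 tracks from an alignment file
#'
#' A read contributes 1 to the bin containing its leftmost aligned base.
#' Unmapped, secondary, supplementary and duplicate-flagged reads are
#' skipped. Reads with mapping quality 0 are counted both in the depth
#' track and in the separate q0 track; the per-region q0 fraction is a
#' mappability red flag on calls.
#'
#' @param path SAM, BAM or CRAM file, coordinate sorted. SAM input is
#'   converted on the fly. CRAM requires the reference registered with
#'   htslib (see [Rsamtools::BamFile]).
#' @param assembly a `genome_assembly`; read chromosome names are matched
#'   against it with "chr"-prefix normalization. Reads on chromosomes not
#'   in the assembly are counted and skipped.
#' @return list with `rd_100` and `q0_100` (`binned_track`s at 100 bp) and
#'   `stats` (reads used / skipped by reason).
#' @export
parse_alignments <- function(path, assembly) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "sam") {
    dest <- tempfile(fileext = "")
    path <- Rsamtools::asBam(path, destination = dest,
                             overwrite = TRUE, indexDestination = FALSE)
  }
  flags <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE,
                                  isDuplicate = FALSE)
  param <- Rsamtools::ScanBamParam(flag = flags,
                                   what = c("rname", "pos", "mapq"))
  res <- Rsamtools::scanBam(path, param = param)[[1]]
  rname <- as.character(res$rname)
  pos <- res$pos
  mapq <- res$mapq
  keep <- !is.na(pos)
  rname <- rname[keep]; pos <- pos[keep]; mapq <- mapq[keep]

  norm <- normalize_chrom(unique(rname), assembly$chroms)
  names(norm) <- unique(rname)
  chrom <- unname(norm[rname])
  n_unknown <- sum(is.na(chrom))
  ok <- !is.na(chrom)
  chrom <- chrom[ok]; pos <- pos[ok]; mapq <- mapq[ok]

  # coordinate-sorted check within each chromosome run
  if (length(pos) > 1L) {
    same <- chrom[-1L] == chrom[-length(chrom)]
    if (any(same & diff(pos) < 0))
      stop("alignment file is not coordinate sorted")
  }

  nb <- setNames(as.integer(ceiling(assembly$lengths / RESOURCE_BIN)),
                 assembly$chroms)
  empty <- lapply(nb, function(n) numeric(n))
  rd <- q0 <- empty
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    b <- pos_to_bin(pos[sel], RESOURCE_BIN)
    inb <- b >= 1L & b <= nb[[ch]]
    tab <- tabulate(b[inb], nbins = nb[[ch]])
    rd[[ch]] <- as.numeric(tab)
    q0b <- b[inb & !is.na(mapq[sel]) & mapq[sel] == 0L]
    q0[[ch]] <- as.numeric(tabulate(q0b, nbins = nb[[ch]]))
  }
  list(
    rd_100 = binned_track(RESOURCE_BIN, rd, assembly$lengths),
    q0_100 = binned_track(RESOURCE_BIN, q0, assembly$lengths),
    stats = list(used = length(pos), skipped_unknown_chrom = n_unknown)
  )
}
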
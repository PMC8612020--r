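# Export: calls as TSV (the 11-column statistics block) or VCF, and
# browser tracks as multi-resolution bedGraph with a manifest.

CALL_TSV_COLUMNS <- c("type", "region", "size", "normRD", "e_val1",
                      "e_val2", "e_val3", "e_val4", "q0", "pN", "dG")

#' Export CNV calls as TSV
#'
#' Writes the canonical 11 columns: type, coordinates, size, normRD,
#' e-val1..4, q0, pN, dG.
#'
#' @param calls a `cnv_calls` data.frame.
#' @param path output file.
#' @return the path, invisibly.
#' @export
export_calls_tsv <- function(calls, path) {
  out <- data.frame(
    type = calls$type,
    region = format_region(calls$chrom, calls$start, calls$end),
    size = calls$size, normRD = calls$normRD,
    e_val1 = calls$e_val1, e_val2 = calls$e_val2,
    e_val3 = calls$e_val3, e_val4 = calls$e_val4,
    q0 = calls$q0, pN = calls$pN, dG = calls$dG)
  if (nrow(calls) == 0L) out <- out[0, CALL_TSV_COLUMNS]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export CNV calls as VCF
#'
#' One symbolic-allele record per call: ALT `<DEL>`/`<DUP>`, INFO keys
#' END, SVTYPE, SVLEN, NRD (normalized depth) and the significance
#' statistics. Includes a minimally valid VCFv4.2 header with contig
#' lines when an assembly is given.
#'
#' @param calls a `cnv_calls` data.frame.
#' @param path output file.
#' @param assembly optional `genome_assembly` for contig header lines.
#' @param sample sample name for the header column.
#' @return the path, invisibly.
#' @export
export_calls_vcf <- function(calls, path, assembly = NULL,
                             sample = "SAMPLE") {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=rdcnv",
    "##ALT=<ID=DEL,Description=\"Deletion\">",
    "##ALT=<ID=DUP,Description=\"Duplication\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position\">",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"SV length\">",
    "##INFO=<ID=NRD,Number=1,Type=Float,Description=\"Normalized read depth\">",
    "##INFO=<ID=EVAL1,Number=1,Type=Float,Description=\"t-test p-value region vs genome\">",
    "##INFO=<ID=EVAL2,Number=1,Type=Float,Description=\"Gaussian-tail p-value\">",
    "##INFO=<ID=Q0,Number=1,Type=Float,Description=\"Fraction of q0 reads\">",
    "##INFO=<ID=PN,Number=1,Type=Float,Description=\"Fraction of N bases\">",
    "##INFO=<ID=DG,Number=1,Type=Float,Description=\"Distance to nearest gap\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
  if (!is.null(assembly))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>", assembly$chroms,
                          as.integer(assembly$lengths)))
  hdr <- c(hdr, paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
                       "\tFORMAT\t", sample))
  rows <- character(nrow(calls))
  for (i in seq_len(nrow(calls))) {
    svtype <- if (calls$type[i] == "deletion") "DEL" else "DUP"
    svlen <- if (svtype == "DEL") -calls$size[i] else calls$size[i]
    info <- sprintf(
      "END=%d;SVTYPE=%s;SVLEN=%d;NRD=%.4g;EVAL1=%.4g;EVAL2=%.4g;Q0=%.4g;PN=%.4g;DG=%s",
      as.integer(calls$end[i]), svtype, as.integer(svlen), calls$normRD[i],
      calls$e_val1[i], calls$e_val2[i], calls$q0[i], calls$pN[i],
      if (is.finite(calls$dG[i])) sprintf("%.4g", calls$dG[i]) else ".")
    rows[i] <- paste(calls$chrom[i], as.integer(calls$start[i]),
                     sprintf("rdcnv_%s_%d", tolower(svtype), i), "N",
                     paste0("<", svtype, ">"), ".", "PASS", info,
                     "GT", "./.", sep = "\t")
  }
  writeLines(c(hdr, rows), path)
  invisible(path)
}

write_bedgraph <- function(track, path, name) {
  lines <- paste0("track type=bedGraph name=\"", name, "\"")
  bs <- track$bin_size
  for (ch in names(track$values)) {
    v <- track$values[[ch]]
    if (length(v) == 0L) next
    keep <- which(!is.na(v))
    if (length(keep) == 0L) next
    start0 <- (keep - 1L) * bs
    end0 <- keep * bs
    if (!is.null(track$lengths))
      end0 <- pmin(end0, track$lengths[[ch]])
    lines <- c(lines, sprintf("%s\t%d\t%d\t%g", ch, start0, end0, v[keep]))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Export browser tracks at 1/10/100-kb resolutions
#'
#' Writes one bedGraph per signal per resolution for each sample, plus a
#' manifest TSV listing every file, so the set can be loaded into a
#' genome browser whose displayed resolution switches with zoom level.
#' Depth tracks are rebinned from the sample's 100-bp base signal on
#' demand; BAF tracks export the per-bin ML BAF.
#'
#' @param samples named list; each element a list with `rd_100` (a 100-bp
#'   `binned_track`) and optionally `baf` (a function(bin_size) returning
#'   a `bin_likelihood`, or a single `bin_likelihood` used as-is).
#' @param out_dir output directory (created).
#' @param resolutions bin sizes in bp (default 1e3, 1e4, 1e5).
#' @return manifest data.frame (also written to `<out_dir>/manifest.tsv`).
#' @export
export_tracks_jbrowse <- function(samples, out_dir,
                                  resolutions = c(1e3, 1e4, 1e5)) {
  stopifnot(is.list(samples), !is.null(names(samples)))
  if (length(samples) == 0L) stop("no samples to export")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  for (sm in names(samples)) {
    s <- samples[[sm]]
    if (is.null(s$rd_100) && is.null(s$baf))
      stop("sample ", sm, ": no tracks to export")
    for (res in resolutions) {
      if (!is.null(s$rd_100)) {
        trk <- rebin(s$rd_100, res)
        f <- file.path(out_dir, sprintf("%s_rd_%d.bedGraph", sm,
                                        as.integer(res)))
        write_bedgraph(trk, f, sprintf("%s RD %d bp", sm, as.integer(res)))
        manifest[[length(manifest) + 1L]] <- data.frame(
          sample = sm, signal = "rd", bin_size = res, file = basename(f))
      }
      if (!is.null(s$baf)) {
        bl <- if (is.function(s$baf)) s$baf(res) else s$baf
        trk <- binned_track(bl$bin_size, bl$ml_baf,
                            lengths = NULL)
        f <- file.path(out_dir, sprintf("%s_baf_%d.bedGraph", sm,
                                        as.integer(res)))
        write_bedgraph(trk, f, sprintf("%s BAF %d bp", sm, as.integer(res)))
        manifest[[length(manifest) + 1L]] <- data.frame(
          sample = sm, signal = "baf", bin_size = res, file = basename(f))
      }
    }
  }
  mf <- do.call(rbind, manifest)
  write.table(mf, file.path(out_dir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  mf
}
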
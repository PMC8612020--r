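# Shared fixture builders. Everything is generated in code at test time;
# no binary fixtures are stored.

# Minimal rd_stats for tests that construct tracks directly.
make_stats <- function(m, s, n_genome = 1000L) {
  structure(list(m = m, s = s, m_gc = rep(NA_real_, 101L),
                 n_bins_genome = n_genome), class = "rd_stats")
}

# Single-chromosome track from a numeric vector.
make_track <- function(v, bin_size = 1000L, chrom = "chr1", len = NULL) {
  if (is.null(len)) len <- length(v) * bin_size
  binned_track(bin_size, setNames(list(as.numeric(v)), chrom),
               setNames(len, chrom))
}

# Write a tiny SAM file; reads is a data.frame with chrom, pos, and
# optionally mapq and flag.
write_test_sam <- function(reads, chrom_lengths,
                           path = tempfile(fileext = ".sam")) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lengths),
                   as.integer(chrom_lengths)))
  if (is.null(reads$mapq)) reads$mapq <- rep(60L, nrow(reads))
  if (is.null(reads$flag)) reads$flag <- rep(0L, nrow(reads))
  body <- if (nrow(reads)) sprintf(
    "r%04d\t%d\t%s\t%d\t%d\t50M\t*\t0\t0\t*\t*",
    seq_len(nrow(reads)), reads$flag, reads$chrom, reads$pos, reads$mapq)
  else character(0)
  writeLines(c(hdr, body), path)
  path
}

# Write a tiny VCF; sites is a data.frame with chrom, pos, ref, alt, gt
# (GT strings), ad_ref, ad_alt, and optionally dp.
write_test_vcf <- function(sites, chrom_lengths,
                           path = tempfile(fileext = ".vcf")) {
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", names(chrom_lengths),
                   as.integer(chrom_lengths)),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"GT\">",
           "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"AD\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"DP\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1")
  if (is.null(sites$dp)) sites$dp <- sites$ad_ref + sites$ad_alt
  body <- sprintf("%s\t%d\t.\t%s\t%s\t99\tPASS\t.\tGT:AD:DP\t%s:%d,%d:%d",
                  sites$chrom, sites$pos, sites$ref, sites$alt, sites$gt,
                  sites$ad_ref, sites$ad_alt, sites$dp)
  writeLines(c(hdr, body), path)
  path
}

# Hand-built call table with the full statistics block.
make_calls <- function(start, end, type = "deletion", chrom = "chr1",
                       e_val1 = 1e-8, q0 = 0, pN = 0, dG = 1e6) {
  n <- length(start)
  structure(data.frame(
    type = rep(type, length.out = n), chrom = chrom, start = start,
    end = end, size = end - start + 1,
    normRD = ifelse(rep(type, length.out = n) == "deletion", 0.5, 1.5),
    e_val1 = rep(e_val1, length.out = n), e_val2 = 1e-8, e_val3 = 1e-8,
    e_val4 = 1e-8, q0 = rep(q0, length.out = n),
    pN = rep(pN, length.out = n), dG = rep(dG, length.out = n),
    stringsAsFactors = FALSE), class = c("cnv_calls", "data.frame"))
}

# Exhaustive least-squares single-change-point fit: the two-segment
# oracle for segmentation accuracy checks.
best_two_segment_sse <- function(x) {
  n <- length(x)
  cs <- cumsum(x); cs2 <- cumsum(x^2)
  best <- Inf; best_k <- NA_integer_
  for (k in 1:(n - 1)) {
    sse_l <- cs2[k] - cs[k]^2 / k
    sse_r <- (cs2[n] - cs2[k]) - (cs[n] - cs[k])^2 / (n - k)
    if (sse_l + sse_r < best) { best <- sse_l + sse_r; best_k <- k }
  }
  list(sse = best, split = best_k)
}

# SSE of a segmentation (data.frame with first_bin/last_bin) on vector x.
segmentation_sse <- function(x, seg) {
  sum(vapply(seq_len(nrow(seg)), function(i) {
    z <- x[seg$first_bin[i]:seg$last_bin[i]]
    sum((z - mean(z))^2)
  }, numeric(1)))
}
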
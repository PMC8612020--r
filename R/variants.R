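# Variant ingestion. Only SNPs and single-letter indels are admitted; each
# retained site stores chromosome, position, reference and alternative
# base, the two allele read counts (ref_i, alt_i), quality, genotype class
# (het 0/1 or hom 1/1) and, when present, total depth DP. These counts are
# everything the BAF machinery needs.

admit_alleles <- function(ref, alt) {
  nr <- nchar(ref); na <- nchar(alt)
  (nr == 1L & na == 1L) |          # SNP
    (nr == 2L & na == 1L) |        # single-letter deletion
    (nr == 1L & na == 2L)          # single-letter insertion
}

#' Import SNPs and single-letter indels from a VCF
#'
#' Multi-allelic records, longer indels and sites without a usable
#' genotype are ignored and tallied. Allele counts come from the AD format
#' field when present, otherwise are reconstructed from DP and an
#' allele-fraction field (AF/VAF/FREQ); sites with neither are skipped.
#'
#' @param path VCF file (plain or bgzipped).
#' @param sample sample column to use (index or name; default first).
#' @param genome genome label passed to the VCF reader (cosmetic).
#' @return a `variant_sites` data.frame: chrom, pos (1-based), ref, alt,
#'   ref_count, alt_count, qual, gt ("het"/"hom"), dp, in_mask (NA until
#'   [apply_strict_mask()]); attribute `skipped` holds tallies.
#' @export
parse_variants <- function(path, sample = 1L, genome = "unknown") {
  vcf <- VariantAnnotation::readVcf(path, genome = genome)
  rr <- SummarizedExperiment::rowRanges(vcf)
  chrom <- as.character(GenomeInfoDb::seqnames(rr))
  pos <- BiocGenerics::start(rr)
  ref <- as.character(rr$REF)
  altl <- rr$ALT
  n_alt <- S4Vectors::elementNROWS(altl)
  alt <- rep(NA_character_, length(ref))
  alt[n_alt == 1L] <- as.character(unlist(altl[n_alt == 1L]))
  qual <- rr$QUAL

  gmat <- VariantAnnotation::geno(vcf)
  if (!"GT" %in% names(gmat)) stop("VCF has no GT field")
  gt_raw <- gmat$GT[, sample]
  gt <- rep(NA_character_, length(gt_raw))
  gt[gt_raw %in% c("0/1", "0|1", "1|0")] <- "het"
  gt[gt_raw %in% c("1/1", "1|1")] <- "hom"

  skipped <- c(multiallelic = sum(n_alt != 1L), not_snp_indel = 0L,
               no_genotype = 0L, no_counts = 0L)
  admit <- !is.na(alt) & admit_alleles(ref, alt)
  skipped[["not_snp_indel"]] <- sum(n_alt == 1L & !admit)
  skipped[["no_genotype"]] <- sum(admit & is.na(gt))
  admit <- admit & !is.na(gt)

  n <- length(ref)
  ref_count <- alt_count <- rep(NA_real_, n)
  dp <- rep(NA_real_, n)
  if ("DP" %in% names(gmat)) dp <- suppressWarnings(as.numeric(gmat$DP[, sample]))
  if ("AD" %in% names(gmat)) {
    ad <- gmat$AD[, sample]
    len2 <- S4Vectors::elementNROWS(ad) >= 2L
    ref_count[len2] <- vapply(ad[len2], function(x) as.numeric(x[1]), 0)
    alt_count[len2] <- vapply(ad[len2], function(x) as.numeric(x[2]), 0)
  }
  need <- admit & is.na(ref_count)
  if (any(need)) {
    af_field <- intersect(c("AF", "VAF", "FREQ"), names(gmat))
    if (length(af_field) && "DP" %in% names(gmat)) {
      af <- suppressWarnings(as.numeric(gmat[[af_field[1]]][, sample]))
      alt_count[need] <- round(dp[need] * af[need])
      ref_count[need] <- dp[need] - alt_count[need]
    }
  }
  no_counts <- admit & (is.na(ref_count) | is.na(alt_count))
  skipped[["no_counts"]] <- sum(no_counts)
  keep <- admit & !no_counts
  sites <- data.frame(
    chrom = chrom[keep], pos = pos[keep], ref = ref[keep], alt = alt[keep],
    ref_count = ref_count[keep], alt_count = alt_count[keep],
    qual = if (is.null(qual)) NA_real_ else as.numeric(qual)[keep],
    gt = gt[keep],
    dp = ifelse(is.na(dp[keep]), ref_count[keep] + alt_count[keep], dp[keep]),
    in_mask = NA, stringsAsFactors = FALSE)
  rownames(sites) <- NULL
  attr(sites, "skipped") <- skipped
  class(sites) <- c("variant_sites", "data.frame")
  sites
}

#' Flag variant sites by strict-mask membership
#'
#' Sets `in_mask` TRUE for sites whose 1-based position falls inside a
#' passed (P) interval. Downstream likelihoods use only in-mask
#' heterozygous sites; everything else is retained but inert.
#'
#' @param sites a `variant_sites` data.frame.
#' @param mask a `strict_mask` from [load_strict_mask()].
#' @return the sites with `in_mask` filled in.
#' @export
apply_strict_mask <- function(sites, mask) {
  sites$in_mask <- FALSE
  for (ch in unique(sites$chrom)) {
    sel <- sites$chrom == ch
    sites$in_mask[sel] <- in_strict_mask(mask, ch, sites$pos[sel])
  }
  sites
}

#' B-allele frequency and minor allele frequency of variant sites
#'
#' BAF = alt / (ref + alt); MAF = min(BAF, 1 - BAF). Sites with zero total
#' depth return NA.
#'
#' @param sites a `variant_sites` data.frame (or anything with
#'   `ref_count` and `alt_count` columns).
#' @return numeric vector.
#' @export
baf <- function(sites) {
  tot <- sites$ref_count + sites$alt_count
  ifelse(tot > 0, sites$alt_count / tot, NA_real_)
}

#' @rdname baf
#' @export
maf <- function(sites) {
  b <- baf(sites)
  pmin(b, 1 - b)
}
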
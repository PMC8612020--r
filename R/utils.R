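#' @keywords internal
"_PACKAGE"

#' @importFrom stats dnorm optim pchisq pnorm rbinom rnorm rpois runif sd
#'   t.test median quantile setNames mad rbeta
#' @importFrom utils read.table write.table head tail
#' @importFrom graphics hist
NULL

# Normalize a chromosome name against a reference set: exact match wins,
# then match with/without a leading "chr". Returns NA_character_ if absent.
normalize_chrom <- function(name, reference) {
  out <- character(length(name))
  for (i in seq_along(name)) {
    nm <- name[i]
    if (nm %in% reference) {
      out[i] <- nm
    } else {
      alt <- if (startsWith(nm, "chr")) sub("^chr", "", nm) else paste0("chr", nm)
      out[i] <- if (alt %in% reference) alt else NA_character_
    }
  }
  out
}

#' Parse a region string
#'
#' Regions are 1-based inclusive, written `"chr:start-end"`. Thousands
#' separators (commas) are tolerated.
#'
#' @param region a single region string.
#' @return list with `chrom`, `start`, `end` (numeric, 1-based inclusive).
#' @examples
#' parse_region("chr1:10,001-20,000")
#' @export
parse_region <- function(region) {
  stopifnot(is.character(region), length(region) == 1L)
  m <- regmatches(region, regexec("^([^:]+):([0-9,]+)-([0-9,]+)$", region))[[1]]
  if (length(m) != 4L)
    stop("malformed region string: ", region, " (expected chr:start-end)")
  start <- as.numeric(gsub(",", "", m[3]))
  end <- as.numeric(gsub(",", "", m[4]))
  if (end < start) stop("region end before start: ", region)
  list(chrom = m[2], start = start, end = end)
}

format_region <- function(chrom, start, end) {
  sprintf("%s:%d-%d", chrom, as.integer(start), as.integer(end))
}

# log(exp(a) + exp(b)) computed stably; vectorized over grids.
logsumexp2 <- function(a, b) {
  m <- pmax(a, b)
  r <- m + log1p(exp(pmin(a, b) - m))
  r[is.infinite(m) & m < 0] <- -Inf
  r
}

# Bin index (1-based) covering 1-based position p at bin size s.
pos_to_bin <- function(p, s) as.integer(ceiling(p / s))

# 1-based [start, end] of bin b (1-based) at bin size s.
bin_span <- function(b, s) cbind(start = (b - 1L) * s + 1, end = b * s)
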
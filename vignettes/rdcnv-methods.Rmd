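---
title: "rdcnv: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{rdcnv: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of its methods: the models and
their assumptions, the tunable parameters with their defaults and the
reasons behind them, what the synthetic-data generator does and does not
emulate, and the numerical and design choices made where more than one
defensible option existed. No empirical claim here goes beyond what the
test suite and `scripts/acceptance.R` themselves compute.

## The two signals

**Read depth (RD).** Under uniform sequencing, the number of reads whose
leftmost aligned base falls in a genomic bin is approximately Poisson with
rate proportional to the local copy number. A one-haplotype deletion halves
the rate, a one-haplotype duplication multiplies it by 1.5. Depth is stored
once at 100-bp resolution; every coarser bin size is an exact sum of the
100-bp bins, so rebinning is restricted to multiples of 100 bp and
conserves totals exactly.

**B-allele frequency (BAF).** At a heterozygous site covered by `ref + alt`
reads, the alt-read count is binomial with success probability equal to the
alt haplotype's copy fraction: 1/2 in diploid regions, 2/3 or 1/3 inside a
one-haplotype duplication (depending on which haplotype carries the alt
allele), 0 or 1 where one haplotype is absent. BAF therefore needs no
normalization, and it responds to copy-number-neutral LOH, which RD cannot
see. Its weakness is sensitivity to systematic mis-mapping; that is what
the strict accessibility mask is for — only variants in "P" (passed)
regions enter any likelihood.

## GC correction and global statistics

Depth depends systematically on bin GC content. The correction is
stratified scaling: each bin's depth is multiplied by `m / m_gc(GC%)`,
where `m_gc` is the mean depth of autosomal bins in the same integer GC%
class (classes with fewer than `min_class_bins = 2` bins stay uncorrected
and flagged, as do all-N bins).

The diploid level `m` and spread `s` come from a Gaussian fit to the
*histogram* of autosomal bin counts rather than from raw moments. The
difference matters: zero-inflated bins (assembly gaps), CNV bins and heavy
tails shift a mean but barely move the histogram peak. The fit is bounded
L-BFGS-B on (amplitude, center, width) over a window of ±6 robust spreads
around the median, initialized at the histogram mode. On GC-structured
genomes the raw histogram can be multi-modal, so the convenience wrapper
`prepare_rd()` refits (m, s) on the *corrected* signal, where a single
diploid peak exists; a constant signal short-circuits to `s = 0` with a
warning. Partial terminal chromosome bins are excluded from the fit and
down-weighted in region means by their covered fraction.

## Mean-shift segmentation

Segmentation is mode seeking in the joint (position, depth) space. The
mean-shift vector at bin `i` is

\[ g_i = \sum_{d} d\, e^{-d^2/2h^2}\,
        e^{-(x_{i+d}-x_i)^2 / 2(\sigma^2_{i+d}+\sigma^2_i)} , \]

with position bandwidth `h` and a depth-dependent signal variance
\(\sigma^2(x) = s^2 \max(x, 0.05\,m)/m\) — the Poisson-like scaling that
makes a half-depth region both lower and tighter than diploid. A boundary
candidate sits wherever the vector flips from leftward to rightward (a
density valley).

Three choices are worth recording:

* **Bandwidth schedule with boundary accumulation.** Partitioning runs at
  `h = 2, 4, …, 128` bins, iterating to a fixed point at each scale with
  segment bins replaced by their segment means. Boundaries found at any
  scale are *retained* as candidates rather than recomputed from scratch:
  a large bandwidth smooths straight across a short event, and attraction
  between same-level flanks on either side of an event would otherwise
  erase a perfectly good small-scale boundary. The cost of keeping noise
  boundaries is paid once, in the merge pass.
* **Significance merge.** Adjacent segments are merged, weakest boundary
  first, while the two-segment z-test under the noise model exceeds
  `alpha = 1e-5`. The threshold is deliberately conservative: boundary
  candidates are selected at extremes of the noise, so nominal levels like
  0.05 would freeze spurious structure. Empirically (see the test suite) a
  constant chromosome collapses to one segment while an `m → m/2` step —
  a ~13-sigma contrast at typical scales — always survives.
* **Boundary refinement.** Each surviving boundary is moved within ±8 bins
  to the local least-squares optimum. This is what brings single
  change-point localization within ±2 bins and keeps the segmentation's
  squared error within 5% of the exhaustive two-segment fit.

The procedure is deterministic for fixed input and parameters. Bins
flagged unusable (all-N, sparse GC class) are excluded from the distance
computations but keep their positions, so segment coordinates stay global;
segments absorb flanking excluded bins to preserve a tiling.

## Calling and the statistics block

Segments with normalized depth below `del_threshold = 0.75` or above
`dup_threshold = 1.25` become candidates (symmetric ±25% around diploid;
both configurable), and adjacent same-type candidates separated by at most
one bin merge before scoring. The per-call statistics are: a one-sample
t-test of region bins against the global mean (e-val1); the Gaussian tail
probability of the region mean under `N(m, s/√n)`, Bonferroni-scaled by
the region-count proxy `genome bins / region bins` and capped at 1
(e-val2); both repeated without the first and last bin, which are the bins
most likely to straddle the true breakpoints (e-val3/4, NA sentinel below
3 bins); the q0 fraction from the 100-bp q0 and depth tracks; the N-base
fraction pN at 100-bp resolution with edge bins weighted by overlap; and
dG, the number of bases strictly between the call and the nearest assembly
gap (0 when overlapping, infinite on gap-free chromosomes).

The "i-test" wording in the source material for e-val1 was read as a
typographical variant of *t*-test; the statistic is two-sided. How e-val2's
multiple-testing scaling was originally defined is not published; the
Bonferroni proxy above is this package's choice.

## BAF likelihood

For unphased counts the site likelihood must be symmetric in (ref, alt):

\[ L(p) \propto p^{a}(1-p)^{r} + p^{r}(1-p)^{a}. \]

Bin likelihoods are pointwise products over in-mask het sites, accumulated
in log space (hundreds of beta factors underflow doubles otherwise) and
max-normalized per bin, evaluated on a `G = 101`-point grid spanning
[0, 0.5] inclusive — the symmetry makes the upper half redundant. The grid
argmax is the reported BAF level; argmax ties break toward the larger `p`,
i.e. toward the balanced null. Homozygous sites are counted per bin but
excluded from the product: they carry no haplotype-balance information,
only the "hets disappeared" signal that per-bin het counts already expose.
Note the symmetrized mode is not exactly `alt/(alt+ref)`: for alt=10,
ref=5 the folded maximum sits near 0.345, pulled slightly off 1/3 by the
mirrored term's tail — tests against a brute-force grid oracle pin this
behaviour down.

The BAF p-value for a region (genotyping output) is a likelihood-ratio
test of `p = 0.5` against the pooled ML estimate, with the chi-square(1)
tail halved because the null sits on the parameter boundary; an ML of
exactly 0.5 returns 1. The original tool names this output without
defining its formula, so the LRT is this package's stand-in and is labeled
as such.

When no alignment is available, mean variant DP per bin is a depth proxy.
Variant-free bins are *missing*, not zero; at 10-kb-and-coarser bins the
proxy tracks true coverage ratios well (the fixture tests reproduce a
1.5× duplication ratio to within a few percent), below that it is noisy.

## Genotyping, filtering, merging

Copy number of a region is `2 · mean RD(region) / mean autosomal RD`, with
the first and last bin weighted by their overlap fraction. The autosomal
mean is the plain mean of usable autosomal bins, per the defining formula;
on toy chromosomes where a planted event is a sizable fraction of the
genome this inflates CN visibly (the README example shows 1.09 for a clean
heterozygous deletion), a bias that vanishes at genome scale.

Call filtering is the conjunction of the five viewer parameters (size
range, max e-val1, max q0, max pN, min dG), idempotent and
order-preserving. Multi-sample merging follows a linear single pass over
calls sorted by (assembly chromosome order, start, end, sample): the first
unprocessed call seeds a group, calls from other samples join on *strict*
reciprocal overlap > 50% (an exact 50% overlap does not merge), every
member is genotyped in the intersection region, and the scan continues
without restarting — the procedure's step 3 is ambiguous on this point;
the linear reading was chosen and is order-independent in the tested
scenarios. Gene annotation is offline, from a name/ID/interval table, and
tags each overlapping gene as inside, covering, or intersecting the left
or right breakpoint.

## The keyed store

All signals live in one file per sample under hierarchical keys
`<signal>/<chrom>/<binsize>`. Only 100-bp base signals are primary data;
anything rebinned or corrected can be deleted and reproduced exactly. The
design brief called for an HDF5 container; no HDF5 R binding is available
in the supported dependency set, so the store is backed by R native
serialization with the same key schema and contracts (bit-identical round
trips, missing-key errors that name the nearest keys). Swapping the
backend would not change the API.

## What the simulator emulates — and what it does not

The fixture generator states a 30× short-read world: Poisson read starts
(100-bp reads), per-100-bp-bin GC composition realized exactly to rounding
(so GC-profile contracts are tight rather than binomially fuzzy), optional
GC-bias multipliers and a mapping-quality-0 fraction, planted events with
per-haplotype copies `(h1, h2)` — deletion (1,0), duplication (2,1),
CNN-LOH (2,0) — and a cell-fraction mixture for subclonal stress tests
(default 1.0). Het density defaults to 1/kb and hom density to ~0.66/kb,
in the range of a human genome's variant density; variant depths are
Poisson around the stated coverage scaled by the local copy state.

Not emulated: sequencing errors, mapping ambiguity (q0 reads are placed
correctly, merely labeled), insert-size structure, reference bias, batch
effects. A green end-to-end test therefore establishes that the engine
recovers events from the stated statistical world, not that it is robust
to every artifact of real data — q0/pN/dG filtering exists precisely
because real data violate this world.

## Known limitations

* Calling operates on segment means only; no boundary-refinement pass at
  sub-bin resolution, so breakpoint precision is one bin.
* e-values for 1–2-bin calls fall back to Gaussian forms (t-tests need
  3+ bins for the trimmed variants); e-val3/4 are NA sentinels there.
* The autosomal-mean CN bias on small genomes, noted above.
* Multi-sample VCFs use one sample column; no joint calling.
* Mosaic events below ~50% cell fraction shift normRD by less than the
  calling thresholds and are out of reach of the default caller, by
  construction.
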
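Package: rdcnv
Title: Copy Number Analysis from Binned Read Depth and B-Allele Frequency
Version: 0.1.0
Authors@R: person("rdcnv", "developers", role = c("aut", "cre"),
    email = "rdcnv@example.org")
Description: Detects and genotypes copy number variants from whole-genome
    sequencing. Read depth is extracted from alignments in 100-bp bins,
    rebinned, corrected for GC bias, segmented with a multi-scale mean-shift
    algorithm, and scored with per-call significance statistics (e-val1-4,
    q0, pN, dG). Heterozygous variants filtered by a strict accessibility
    mask provide a complementary B-allele frequency signal through
    per-bin symmetrized-beta likelihoods, enabling detection of
    copy-number-neutral loss of heterozygosity and genotyping of arbitrary
    regions. Includes a keyed signal store, multi-sample call merging,
    browser-track export, and a synthetic fixture generator with planted
    events for offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    graphics,
    utils,
    tools,
    jsonlite,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    Biostrings,
    Rsamtools,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
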
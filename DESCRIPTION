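Package: xallele
Title: Allele-Specific Analysis of Skewed X Inactivation in F1 Hybrid Cells
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for allele-specific sequencing analysis in F1 hybrid mouse
    systems with completely skewed X chromosome inactivation. Builds a SNP
    substituted pseudo-genome for the alternate strain, filters and segregates
    aligned reads into reference-allele, alternate-allele and ambiguous
    categories using the strain-diagnostic SNPs they cover, aggregates
    classified reads into fixed-width browser tracks, computes TSS-anchored
    metagene enrichment profiles with distribution-shift statistics, quantifies
    gene-level allelic expression (SRPM, RPKM, depth adjustment, escape-gene
    subsets), predicts allele-discriminating restriction digests in silico, and
    analyses per-nucleus FISH nucleolar-association frequencies against a
    diploid background model. A synthetic-data module generates fully specified
    toy hybrid datasets with ground truth so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    Rsamtools,
    rtracklayer,
    S4Vectors,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
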
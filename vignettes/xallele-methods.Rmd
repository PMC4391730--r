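---
title: "xallele: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{xallele: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of the science it implements:
what is modeled, which knobs matter, what the synthetic data does and does
not emulate, and where a genuinely open design choice was settled. No
empirical claim is made here that the test suite or
`scripts/acceptance.R` does not itself compute.

## 1. The analysis model

The package targets F1 hybrid systems with completely skewed X chromosome
inactivation: every cell silences the X from the same parental strain, and
the two haplotypes differ by a single-nucleotide substitution roughly every
50–100 bp. Three consequences structure the design:

1. **A substitution-only pseudo-genome.** Because only SNVs are modeled,
   the alternate-strain genome obtained by substituting alleles into the
   reference is *coordinate-identical* to it. Any interval means the same
   thing in both genomes, dual alignments of one read can be compared by
   position, and no liftover is ever needed. Indels and multi-nucleotide
   variants are rejected loudly rather than dropped silently: accepting
   them would break the coordinate-sharing contract everywhere downstream.

2. **Three-way read classification.** A retained read is REF if it carries
   at least one reference-strain SNP base and no alternate-strain base, ALT
   in the mirror case, and AMBIGUOUS otherwise (no SNP covered, both
   alleles seen, or only bases matching neither allele). A base matching
   *neither* allele — usually a sequencing error — is counted as
   uninformative (`n_other_snps`) rather than disqualifying: the category
   definition references only the two allele classes, so a read whose
   remaining SNPs are uniformly reference-matching stays REF. Both
   accountings remain recoverable from the per-read counts.

3. **Library-scale normalization.** Allelic expression is reported in SRPM
   (SNP reads per 10⁷ mapped reads) and cross-condition comparisons divide
   the deeper library's counts by the depth ratio f = N_b/N_a. The SRPM
   denominator is the library's *total* mapped reads, not the allelic
   subset — the literal reading of the unit — so SRPM values are comparable
   across genes with different SNP densities.

## 2. Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `mapq_min` | 30 | phred-scaled MAPQ | the uniqueness threshold used for allele-specific filtering |
| `window_size` | 100 | bp | the browser-track resolution for allelic coverage |
| `rpkm_min` | 1 | RPKM | expressed-gene filter applied in either condition |
| `srpm_min` | 5 | SRPM | Xi-informative ("subset 1") threshold, satisfied in either condition or both |
| `fold_cutoffs` | 1.25, 1.5, 2.0 | fold | regulation calls are reported at all three |
| metagene dialect | 500/100 | bp window/step | dense-array end-analysis grid; `agilent` selects 600/200 |
| gene-body interval | +1000..+2000 | bp from TSS, strand-aware | where the repressive-mark shift is quantified |
| `snp_rate` | 1/75 | per bp | middle of the observed 1 per 50–100 bp hybrid density |
| `read_length` | 100 | nt | the longer of the two read formats used in such studies |
| `allelic_skew` | 0.16 | fraction | Xi share of informative reads for a partially silenced locus |
| `error_rate` | 0.001 | per base | typical Illumina substitution rate; substitution-only |

The Xi orientation (`xi_allele = "REF"` or `"ALT"`) is deliberately a
*required* argument wherever REF/ALT is mapped to Xi/Xa: which strain
carries the inactive X differs between systems (it can be the reference
strain in a cell line and the alternate strain in a tissue), so a default
would silently flip every Xi/Xa ratio.

## 3. What the synthetic generator states — and what it does not

`simulate_genome_pair()` draws an i.i.d. uniform-base genome and places
SNPs as a per-base Bernoulli process; `simulate_reads()` draws single-end,
fixed-length reads uniformly per chromosome, chooses the source haplotype
per read with the chromosome's skew probability, applies substitution
errors, and emits alignments *at the true coordinates* with a fixed MAPQ.
The off-the-shelf alignment step is bypassed on purpose: the package's
contribution begins after alignment, and emitting truth-tagged SAM makes
every downstream stage testable against ground truth.

`simulate_enrichment()` draws per-gene enrichment levels lognormally around
a class baseline (X-linked higher than autosomal, escape genes near zero),
multiplies the X-gene mean by (1 − `x_effect`) in the knockdown track, and
adds per-bin Gaussian noise. The two conditions are drawn *independently* —
two separate experiments — so with `x_effect = 0` they are exchangeable and
the shift test's p-values can be checked for uniformity. Per-gene
reproducibility between conditions (paired structure) is consequently not
modeled; the scatter-plot demonstrations construct their own paired data.

Not modeled, by declaration: base-quality variation, paired-end fragments,
indels, PCR duplicates, library-complexity effects, mappability structure,
and genuine biological covariance between conditions. A green test on this
generator therefore establishes algorithmic correctness (classification,
counting, conservation, statistical calibration) — not robustness to
real-data artifacts such as reference bias or duplicated regions.

## 4. Numerical and procedural choices

* **Window assignment by 5′-most aligned base.** Each read increments
  exactly one window. Point assignment makes totals conserved and window
  refinement exact (halving the width and re-summing reproduces the coarse
  track bit-for-bit, which the tests assert). Overlap-weighted spreading
  would have neither property.
* **SNP evaluation honors the CIGAR.** Only M/=/X blocks are walked;
  soft-clipped and inserted bases never testify, deleted/skipped reference
  positions are never queried. Base qualities are not consulted (no floor),
  reproducing the behavior of the original filtering, which relied on MAPQ
  alone.
* **Dual-alignment tie-break.** A read passing the filter in both genomes
  keeps the higher-MAPQ record; at equal MAPQ the coordinates must agree
  (coordinate-identical genomes) and the reference record is kept. Equal-
  MAPQ disagreements go to a discordant-read report and are dropped.
* **Metagene averaging order.** Per-gene window means are averaged over
  genes ("per-gene-first"), so every covered gene contributes equally
  regardless of its probe or coverage density. Windows with no signal are
  excluded from that gene's mean, and genes with no covered window are
  omitted (with a count), never zero-imputed: a zero is a strong claim on a
  log-ratio scale.
* **Significance stand-in.** The original pipeline delegated differential
  significance to an external model (Cuffdiff2); that model is *not*
  reimplemented. `classify_genes()` defaults to a two-sided binomial test
  of the raw condition-b count against the combined count given the depth
  ratio, BH-corrected at 0.05, and accepts any user function
  `f(raw_a, raw_b, depth_factor)` in its place. Fold changes use a
  0.5-count continuity offset so zero-count genes remain finite.
* **SRPM threshold on raw counts.** Whether the ≥5 SRPM subset threshold
  applies before or after depth adjustment is unstated in the source
  material; the default is raw (each library judged by its own evidence),
  with `srpm_on_adjusted = TRUE` to switch.
* **RFLP cut geometry.** Sites are matched with IUPAC degeneracy on both
  strands; each site occurrence yields one double-strand cut position:
  `cut_offset` bases from the match start for forward-orientation matches
  and `L − cut_offset` for reverse-orientation matches, deduplicated. For
  palindromic sites with an off-centre cut offset the physical break is
  staggered and a single position is inherently strand-dependent; the
  forward-strand convention is used, which is why exact reverse-complement
  mirror symmetry is asserted only for non-palindromic sites and
  centre-cutting palindromes. Fragment-length conservation and the
  brute-force position oracle hold in all cases.
* **Degenerate statistics.** The one-sample t-test of all-ratios-equal-the-
  null returns statistic 0 and p = 1 instead of erroring on zero variance;
  the chi-square uses no continuity correction (matching the hand-computed
  Pearson value); association intervals are Wilson rather than Wald so
  0/n and n/n give informative bounds.
* **Low-MAPQ whitelist.** Genes whose exons cross-map to near-identical
  regions (depressing MAPQ below the floor) can be exempted by gene id;
  reads overlapping a whitelisted gene's exons are retained regardless of
  MAPQ. No coordinates are hard-coded.
* **FISH background.** Both the additive extrapolation (ploidy × p, the
  form used in the source analysis) and the exact complement
  1 − (1 − p)^ploidy are always reported; at ploidy 2 the additive form
  overestimates by exactly p², which the tests assert algebraically. No
  claim is made about which better models the biology.
* **SNP-source conflicts.** Where two SNP catalogs disagree on an allele,
  `validate_snps()` flags the conflict and `build_pseudogenome()` refuses
  to proceed; reconciliation is the caller's decision, not a silent merge.

## 5. Known limitations

* Reference bias is out of reach of the simulator: simulated alignments
  are emitted at true coordinates, so the dual-alignment reconciliation
  path is exercised structurally (tie-breaks, discordance) but not under
  realistic mapping asymmetry.
* RPKM is computed from total exonic reads over the exon-length union; the
  original pipeline's transcript-model-aware RPKM may differ for genes with
  complex isoform structure.
* The windowed tracks ignore strand for counting (appropriate for ChIP
  fragments); stranded RNA protocols would need the recorded strand field.
* `screen_enzymes()` ranks by a minimum fragment-length difference as a gel
  resolvability proxy; it does not model electrophoresis mobility.
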
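# one SNP at chr1:5 (C ref / T alt), one at chr1:12 (A ref / G alt)
toy_snps <- function() snp_table(c("chr1", "chr1"), c(5L, 12L),
                                 c("C", "A"), c("T", "G"))

test_that("classify_reads covers the four canonical single-read cases", {
  snps <- toy_snps()
  aln <- alignments(
    qname = c("ref1", "alt1", "both", "none", "err", "offchrom"),
    chrom = c(rep("chr1", 5), "chr9"),
    pos = c(1L, 1L, 1L, 20L, 1L, 1L),
    seq = c("AAAACAAAAA",   # base C at pos 5 -> REF
            "AAAATAAAAA",   # base T at pos 5 -> ALT
            "AAAACAAAAAAGAA",  # C at 5 (ref) + G at 12 (alt) -> AMBIGUOUS
            "AAAAAAAAAA",   # covers no SNP -> AMBIGUOUS
            "AAAAGAAAAA",   # G at 5 matches neither -> AMBIGUOUS
            "AAAACAAAAA"))  # chromosome absent from SNP table
  cl <- classify_reads(aln, snps)
  expect_equal(cl$category,
               c("REF", "ALT", "AMBIGUOUS", "AMBIGUOUS", "AMBIGUOUS",
                 "AMBIGUOUS"))
  expect_equal(cl$n_ref_snps, c(1L, 0L, 1L, 0L, 0L, 0L))
  expect_equal(cl$n_alt_snps, c(0L, 1L, 1L, 0L, 0L, 0L))
  expect_equal(cl$n_other_snps, c(0L, 0L, 0L, 0L, 1L, 0L))
})

test_that("classification honors CIGAR: clips and deletions shift SNP lookup", {
  snps <- toy_snps()
  # 3 soft-clipped bases, alignment starts at ref pos 3: SNP at ref 5 is the
  # 3rd aligned base, i.e. query base 6
  aln <- alignments("clip", "chr1", 3L, "GGGAACAA", cigar = "3S5M")
  expect_equal(classify_reads(aln, snps)$category, "REF")
  # clipped bases never count: SNP under the clip only -> AMBIGUOUS
  aln2 <- alignments("cliponly", "chr1", 6L, "GTGAAAA", cigar = "2S5M")
  cl2 <- classify_reads(aln2, snps)
  expect_equal(cl2$n_ref_snps + cl2$n_alt_snps + cl2$n_other_snps, 0L)
  # deletion: read spans ref 1-12 with 4M4D4M; SNP at 12 is query base 8
  aln3 <- alignments("del", "chr1", 1L, "AAAAAAAG", cigar = "4M4D4M")
  expect_equal(classify_reads(aln3, snps)$category, "ALT")
  # insertion shifts query the other way: 4M2I4M, ref 1-8, SNP 5 = query 7
  aln4 <- alignments("ins", "chr1", 1L, "AAAAGGCAAAAA", cigar = "4M2I6M")
  cl4 <- classify_reads(aln4, snps)
  expect_equal(cl4$n_ref_snps, 1L)
})

test_that("filter_alignments: MAPQ threshold, uniqueness, whitelist rescue", {
  genes <- toy_genes()
  aln <- alignments(qname = c("q30", "q29", "q5wl", "q5", "unmapped", "multi",
                              "multi"),
                    chrom = "chr1",
                    pos = c(500L, 500L, 10500L, 500L, 500L, 500L, 700L),
                    seq = strrep("A", 50),
                    mapq = c(30L, 29L, 5L, 5L, 60L, 60L, 60L),
                    flag = c(0L, 0L, 0L, 0L, 4L, 0L, 256L))
  pol <- filter_policy(mapq_min = 30L, low_mapq_whitelist = "gA")
  kept <- filter_alignments(aln, pol, genes)
  # q30 kept (boundary), q29 dropped, q5wl rescued by whitelisted exon
  # overlap, q5 dropped, unmapped dropped, multi dropped (secondary record)
  expect_setequal(kept$qname, c("q30", "q5wl"))
  # unmapped-only input: empty output with a warning
  expect_warning(out <- filter_alignments(
    alignments("u", "chr1", 1L, "AAAA", flag = 4L), filter_policy()),
    "no mapped")
  expect_equal(nrow(out), 0L)
})

test_that("partition and ref/alt symmetry hold on simulated data", {
  cfg <- sim_config(genome_length = 30000L, n_chromosomes = 1L,
                    snp_rate = 1 / 75, coverage = 10, error_rate = 0.005,
                    seed = 21)
  gp <- simulate_genome_pair(cfg)
  sim <- simulate_reads(list(reference = gp$reference), gp$snps, cfg,
                        region_skew = 0.4)
  cl <- classify_reads(sim$alignments, gp$snps)
  tab <- table(factor(cl$category, c("REF", "ALT", "AMBIGUOUS")))
  expect_equal(sum(tab), nrow(sim$alignments))
  # swapping alleles swaps REF and ALT exactly
  swapped <- snp_table(gp$snps$chrom, gp$snps$pos, gp$snps$alt, gp$snps$ref)
  cl2 <- classify_reads(sim$alignments, swapped)
  expect_equal(sum(cl2$category == "REF"), unname(tab["ALT"]))
  expect_equal(sum(cl2$category == "ALT"), unname(tab["REF"]))
  expect_equal(cl2$n_ref_snps, cl$n_alt_snps)
})

test_that("oracle equivalence on error-free reads; errors within bound", {
  cfg0 <- sim_config(genome_length = 30000L, n_chromosomes = 1L,
                     snp_rate = 1 / 75, coverage = 10, error_rate = 0,
                     seed = 22)
  gp <- simulate_genome_pair(cfg0)
  sim <- simulate_reads(list(reference = gp$reference), gp$snps, cfg0,
                        region_skew = 0.16)
  cl <- classify_reads(sim$alignments, gp$snps)
  covered <- cl$n_ref_snps + cl$n_alt_snps + cl$n_other_snps > 0
  # every SNP-covering read classified to its true haplotype
  expect_true(all(cl$category[covered] ==
                  ifelse(sim$truth$true_hap[covered] == "A", "ALT", "REF")))
  expect_true(all(cl$category[!covered] == "AMBIGUOUS"))

  # monotone robustness: with per-base error e, a read changes category only
  # if >= 1 of its covered SNP bases is corrupted; bound the changed fraction
  # by 3x the expected number of corrupted SNP bases
  e <- 0.01
  cfg1 <- cfg0; cfg1$error_rate <- e
  sim1 <- simulate_reads(list(reference = gp$reference), gp$snps, cfg1,
                         region_skew = 0.16)
  cl1 <- classify_reads(sim1$alignments, gp$snps)
  changed <- sum(cl1$category != cl$category)
  n_snp_bases <- sum(cl$n_ref_snps + cl$n_alt_snps + cl$n_other_snps)
  expect_lt(changed, 3 * e * n_snp_bases + 10)
})

test_that("reconcile_dual_alignments keeps each read once with tie rules", {
  pol <- filter_policy(mapq_min = 30L)
  a <- alignments(qname = c("both_tie", "both_pseudo", "ref_only",
                            "fail_both", "tie_discordant"),
                  chrom = "chr1", pos = c(100L, 100L, 100L, 100L, 100L),
                  seq = strrep("A", 36),
                  mapq = c(60L, 40L, 60L, 10L, 60L))
  b <- alignments(qname = c("both_tie", "both_pseudo", "pseudo_only",
                            "fail_both", "tie_discordant"),
                  chrom = "chr1", pos = c(100L, 100L, 200L, 100L, 900L),
                  seq = strrep("A", 36),
                  mapq = c(60L, 60L, 60L, 10L, 60L))
  out <- reconcile_dual_alignments(a, b, pol)
  got <- out$alignments
  expect_equal(anyDuplicated(got$qname), 0L)
  expect_equal(got$genome_of_alignment[got$qname == "both_tie"], "reference")
  expect_equal(got$genome_of_alignment[got$qname == "both_pseudo"], "pseudo")
  expect_equal(got$genome_of_alignment[got$qname == "ref_only"], "reference")
  expect_equal(got$genome_of_alignment[got$qname == "pseudo_only"], "pseudo")
  expect_false("fail_both" %in% got$qname)
  expect_false("tie_discordant" %in% got$qname)
  expect_equal(out$discordant$qname, "tie_discordant")
})
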
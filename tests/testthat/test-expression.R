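mk_cl <- function(chrom, start, category, strand = "+", length = 36L) {
  n <- length(start)
  structure(data.frame(read_id = sprintf("r%d", seq_len(n)), chrom = chrom,
                       start = as.integer(start), length = as.integer(length),
                       strand = strand, mapq = 60L,
                       genome_of_alignment = "reference",
                       n_ref_snps = 0L, n_alt_snps = 0L, n_other_snps = 0L,
                       category = category, stringsAsFactors = FALSE),
            class = c("classified_reads", "data.frame"))
}

test_that("count_gene_alleles: exon rule, intron exception, SRPM units", {
  genes <- gene_model(c("g1", "firre"), "chrX", "+", c(1000L, 5000L),
                      exon_start = list(1000L, c(5000L, 7000L)),
                      exon_end = list(2000L, c(5500L, 7500L)),
                      chrom_class = "X")
  cl <- mk_cl("chrX",
              start = c(1200L, 1300L, 1400L, 6000L, 5100L, 100L),
              category = c("ALT", "ALT", "REF", "ALT", "REF", "ALT"))
  # library of 10 M mapped reads; Xi is the ALT strain
  expr <- count_gene_alleles(cl, genes, xi_allele = "ALT",
                             total_mapped = 1e7)
  # g1: 2 ALT(Xi) + 1 REF(Xa); intronic read at 6000 not counted for firre
  expect_equal(expr$snp_reads_xi, c(2L, 0L))
  expect_equal(expr$snp_reads_xa, c(1L, 1L))
  # 5 Xi SNP-reads in a 10 M library would be 5 SRPM; here 2 -> 2 SRPM
  expect_equal(expr$srpm_xi, c(2, 0))
  # with the intron exception the gene-body read is counted
  expr2 <- count_gene_alleles(cl, genes, xi_allele = "ALT",
                              total_mapped = 1e7,
                              include_introns = "firre")
  expect_equal(expr2$snp_reads_xi[2], 1L)
  # zero-SNP-read gene retained with zeros
  g3 <- rbind(genes, gene_model("empty", "chrX", "+", 9000L, 9000L, 9500L,
                                chrom_class = "X"))
  expr3 <- count_gene_alleles(cl, g3, xi_allele = "ALT", total_mapped = 1e7)
  expect_equal(expr3$srpm_xi[3], 0)
  expect_equal(expr3$total_reads[3], 0L)
  # rpkm: g1 has 3 exonic reads over 1.001 kb in a 10 M library
  expect_equal(expr$rpkm[1], 3 / 1.001 / 10, tolerance = 1e-9)
})

test_that("depth adjustment reproduces the library-ratio arithmetic", {
  adj <- depth_adjustment(22.3e6, 23.7e6)
  expect_equal(round(adj$factor, 2), 1.06)
  genes <- gene_model("g", "chrX", "+", 100L, 100L, 400L, chrom_class = "X")
  cl <- mk_cl("chrX", rep(150L, 106L), rep("ALT", 106L))
  expr <- count_gene_alleles(cl, genes, xi_allele = "ALT",
                             total_mapped = 23.7e6)
  out <- adjust_depth(expr, depth_adjustment(1e6, 1.06e6))
  expect_equal(out$snp_reads_xi, 100)           # 106 / 1.06
  expect_equal(out$snp_reads_xi_raw, 106L)
  # equal depths: factor 1, adjusted = raw
  out2 <- adjust_depth(expr, depth_adjustment(5e6, 5e6))
  expect_equal(out2$snp_reads_xi, out2$snp_reads_xi_raw)
  expect_error(adjust_depth(expr, structure(list(factor = 0),
                                            class = "depth_adjustment")),
               "factor")
})

test_that("xi_xa_ratio handles the headline, zero and undefined cases", {
  expect_equal(xi_xa_ratio(list(snp_reads_xi = 16, snp_reads_xa = 100)), 0.16)
  expect_equal(xi_xa_ratio(list(snp_reads_xi = 0, snp_reads_xa = 50)), 0)
  expect_warning(r <- xi_xa_ratio(list(snp_reads_xi = 4, snp_reads_xa = 0)),
                 "undefined")
  expect_true(is.na(r))
})

test_that("allelic fraction recovery is unbiased across true Xi fractions", {
  # 100x coverage; per-gene Xi fractions derived from xi/xa ratios
  for (f in c(0, 0.05, 0.16, 0.5)) {
    cfg <- sim_config(genome_length = 50000L, n_chromosomes = 1L,
                      snp_rate = 1 / 75, coverage = 100, error_rate = 0,
                      seed = 100 + round(1000 * f))
    gp <- simulate_genome_pair(cfg)
    sim <- simulate_reads(list(reference = gp$reference), gp$snps, cfg,
                          region_skew = f)
    cl <- classify_reads(sim$alignments, gp$snps)
    genes <- gene_model(sprintf("g%02d", 1:50), "chrX", "+",
                        tss = 1000L * (0:49) + 1L,
                        exon_start = as.list(1000L * (0:49) + 1L),
                        exon_end = as.list(1000L * (0:49) + 900L),
                        chrom_class = "X")
    expr <- count_gene_alleles(cl, genes, xi_allele = "ALT",
                               total_mapped = nrow(cl))
    ratio <- expr$snp_reads_xi / pmax(expr$snp_reads_xa, 1L)
    frac <- ratio / (1 + ratio)
    expect_lt(abs(mean(frac) - f), 0.01)
  }
})

test_that("classify_genes: expression filter, subsets, fold calls, summary", {
  ng <- 20L
  genes <- gene_model(sprintf("g%02d", 1:ng),
                      chrom = rep(c("chrX", "chr1"), each = 10L),
                      strand = "+", tss = rep(1000L * (1:10), 2L),
                      exon_start = as.list(rep(1000L * (1:10), 2L)),
                      exon_end = as.list(rep(1000L * (1:10) + 999L, 2L)),
                      chrom_class = rep(c("X", "autosome"), each = 10L))
  base <- data.frame(gene_id = genes$gene_id,
                     chrom_class = genes$chrom_class,
                     xci_status = genes$xci_status, stringsAsFactors = FALSE)
  mk_expr <- function(xi, xa, total, rpkm, total_mapped = 1e7) {
    e <- base
    e$snp_reads_xi <- xi; e$snp_reads_xa <- xa; e$total_reads <- total
    e$rpkm <- rpkm
    e$srpm_xi <- xi * 1e7 / total_mapped
    e$srpm_xa <- xa * 1e7 / total_mapped
    e$condition <- "c"
    attr(e, "total_mapped") <- total_mapped
    class(e) <- c("allelic_expression", "data.frame")
    e
  }
  rpkm <- c(rep(5, 9), 0.9, rep(5, 9), 0.9)   # one gene per class below 1
  xi_a <- c(rep(6L, 3L), rep(0L, 17L))         # 3 X genes Xi-informative in a
  tot_a <- rep(200L, ng)
  tot_b <- tot_a
  tot_b[1] <- 400L    # up 2.0x
  tot_b[4] <- 100L    # down 2.0x
  tot_b[11] <- 143L   # down 1.40x (between the 1.25 and 1.5 cutoffs)
  ea <- mk_expr(xi_a, rep(10L, ng), tot_a, rpkm)
  eb <- mk_expr(rep(0L, ng), rep(10L, ng), tot_b, rpkm)
  res <- classify_genes(ea, eb, rpkm_min = 1, srpm_min = 5,
                        cutoffs = c(1.25, 1.5, 2))
  calls <- res$calls
  # rpkm 0.9/0.9 genes excluded
  expect_false(any(c("g10", "g20") %in% calls$gene_id))
  # subsets partition the expressed X genes
  xcalls <- calls[calls$cutoff == 1.25 & grepl("^X", calls$group), ]
  expect_setequal(xcalls$gene_id[xcalls$group == "X_subset1"],
                  c("g01", "g02", "g03"))
  expect_equal(sum(xcalls$group == "X_subset2"), 6L)
  # srpm threshold satisfied in either condition counts (here: condition a)
  expect_true("g01" %in% xcalls$gene_id[xcalls$group == "X_subset1"])
  # direction calls respect cutoff and significance jointly
  g1 <- calls[calls$gene_id == "g01", ]
  expect_equal(g1$direction[g1$cutoff == 1.25], "up")
  expect_equal(g1$direction[g1$cutoff == 2], "unchanged")  # fold not > 2
  g4 <- calls[calls$gene_id == "g04", ]
  expect_equal(g4$direction[g4$cutoff == 1.25], "down")
  g11 <- calls[calls$gene_id == "g11", ]
  expect_equal(g11$direction[g11$cutoff == 1.5], "unchanged")
  expect_equal(g11$direction[g11$cutoff == 1.25], "down")
  # group summary percentages are nearest-integer
  s <- res$summary
  row <- s[s$group == "X_subset1" & s$cutoff == 1.25, ]
  expect_equal(row$n, 3L)
  expect_equal(row$pct_up, round(100 * row$n_up / row$n))
})

test_that("fold changes are invariant to a common depth scaling", {
  # multiplying both libraries' depths by c leaves the adjusted comparison
  # unchanged: factor is a ratio
  f1 <- depth_adjustment(1e6, 2e6)$factor
  f2 <- depth_adjustment(3e6, 6e6)$factor
  expect_equal(f1, f2)
  expect_equal(depth_adjustment(22.3e6, 23.7e6)$factor,
               depth_adjustment(22.3, 23.7)$factor)
})
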
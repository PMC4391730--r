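test_that("metagene grid geometry and constant-signal identity", {
  genes <- toy_genes()
  sig <- const_signal(c("chr1", "chrX"), 50000L, score = 1)
  prof <- metagene_profile(sig, genes, window = 500L, step = 100L,
                           span = 3000L)
  expect_equal(nrow(prof), 61L)  # offsets -3000..+3000 every 100 bp
  expect_equal(prof$offset, seq(-3000L, 3000L, 100L))
  expect_equal(prof$mean_enrichment, rep(1, 61L))
  expect_equal(prof$n_genes, rep(4L, 61L))
  # agilent dialect: 600/200 -> 31 offsets
  expect_equal(nrow(metagene_profile(sig, genes, dialect = "agilent")), 31L)
  expect_error(metagene_profile(sig, genes, window = 50L, step = 100L),
               "window")
})

test_that("minus-strand genes are mirrored: upstream signal at + offsets", {
  g <- gene_model("gm", "chr1", "-", 5000L, 4000L, 5000L,
                  chrom_class = "autosome")
  # signal only genomically upstream of (i.e. at coordinates below) the TSS
  sig <- data.frame(chrom = "chr1", start = 0L, end = 4999L, score = 2)
  prof <- metagene_profile(sig, g, window = 500L, step = 500L, span = 2000L)
  expect_equal(prof$mean_enrichment[prof$offset == 1500L], 2)
  expect_true(is.na(prof$mean_enrichment[prof$offset == -1500L]))
})

test_that("gene_body_enrichment is a coverage-weighted strand-aware mean", {
  gp <- gene_model("g1", "chr1", "+", 1000L, 1000L, 4000L)
  sig <- data.frame(chrom = "chr1", start = c(1999L, 2499L),
                    end = c(2499L, 2999L), score = c(1, 3))
  # probes 1.0 and 3.0 covering halves of [tss+1000, tss+2000) -> 2.0
  expect_equal(gene_body_enrichment(sig, gp)$enrichment, 2)
  # signal exactly on the interval
  sig2 <- data.frame(chrom = "chr1", start = 1999L, end = 2999L, score = 2)
  expect_equal(gene_body_enrichment(sig2, gp)$enrichment, 2)
  # minus-strand gene: interval is [tss-2000, tss-1000) genomically
  gm <- gene_model("g2", "chr1", "-", 5000L, 2000L, 5000L)
  sigm <- data.frame(chrom = "chr1", start = c(3000L, 4000L),
                     end = c(4000L, 4500L), score = c(7, 0))
  expect_equal(gene_body_enrichment(sigm, gm)$enrichment, 7)
  # uncovered genes omitted, counted
  far <- gene_model("g3", "chr5", "+", 1000L, 1000L, 2000L)
  gb <- gene_body_enrichment(sig, rbind(gp, far))
  expect_equal(nrow(gb), 1L)
  expect_equal(attr(gb, "n_uncovered"), 1L)
})

test_that("strand symmetry: mirroring the genome leaves profiles unchanged", {
  genes <- toy_genes()
  L <- 50000L
  set.seed(41)
  sig <- data.frame(chrom = rep(c("chr1", "chrX"), each = 500L),
                    start = rep(seq(0L, 49900L, 100L), 2L))
  sig$end <- sig$start + 100L
  sig$score <- rnorm(nrow(sig))
  mirror_sig <- data.frame(chrom = sig$chrom, start = L - sig$end,
                           end = L - sig$start, score = sig$score)
  mirror_genes <- genes
  mirror_genes$strand <- ifelse(genes$strand == "+", "-", "+")
  mirror_genes$tss <- L + 1L - genes$tss
  mirror_genes$exon_start <- lapply(genes$exon_end, function(e) L + 1L - e)
  mirror_genes$exon_end <- lapply(genes$exon_start, function(s) L + 1L - s)
  p1 <- metagene_profile(sig, genes)
  p2 <- metagene_profile(mirror_sig, mirror_genes)
  expect_equal(p2$mean_enrichment, p1$mean_enrichment, tolerance = 1e-12)
  g1 <- gene_body_enrichment(sig, genes)
  g2 <- gene_body_enrichment(mirror_sig, mirror_genes)
  expect_equal(g2$enrichment, g1$enrichment, tolerance = 1e-12)
})

test_that("shift_test: identity, KS oracle on shifted data, x_effect sign", {
  set.seed(42)
  a <- rnorm(100)
  same <- shift_test(a, a)
  expect_equal(same$ks_statistic, 0)
  expect_equal(same$percent_change, 0)
  # constant location shift: statistic equals brute-force ECDF computation
  b <- a + 0.5
  st <- shift_test(a, b)
  expect_equal(st$ks_statistic, bf_ks_stat(a, b))
  expect_error(shift_test(a[1:2], b), "at least 3")
  # simulated 16% X-specific effect: percent change near -16, X significant,
  # autosomes not
  genes <- simulate_genes(n_x = 300L, n_autosome = 300L, seed = 5,
                          escape_fraction = 0)
  sig <- simulate_enrichment(genes, x_effect = 0.16, seed = 43)
  gb_c <- gene_body_enrichment(sig$control, genes)
  gb_k <- gene_body_enrichment(sig$knockdown, genes)
  isx_c <- gb_c$chrom_class == "X"; isx_k <- gb_k$chrom_class == "X"
  stx <- shift_test(gb_c$enrichment[isx_c], gb_k$enrichment[isx_k])
  expect_lt(stx$p_value, 0.05)
  expect_lt(abs(stx$percent_change + 16), 5)
  sta <- shift_test(gb_c$enrichment[!isx_c], gb_k$enrichment[!isx_k])
  expect_gt(sta$p_value, 0.05)
})

test_that("null calibration: p-values uniform under exchangeability (DKW)", {
  # both summaries drawn from the same distribution, at the ~600-gene scale
  # the shift test is used at; 1000 replicates
  set.seed(44)
  reps <- 1000L
  p <- vapply(seq_len(reps), function(i)
    shift_test(rnorm(600), rnorm(600))$p_value, 0)
  grid <- seq(0.05, 0.95, 0.05)
  dev <- max(abs(vapply(grid, function(t) mean(p <= t), 0) - grid))
  # DKW bound at alpha = 0.001 for 1000 replicates, plus slack for the
  # conservativeness of the asymptotic two-sample KS null at finite n
  expect_lt(dev, sqrt(log(2 / 0.001) / (2 * reps)) + 0.02)
})

test_that("scatter_summary recovers trend slopes per chromosome class", {
  genes <- toy_genes()
  a <- data.frame(gene_id = genes$gene_id, chrom_class = genes$chrom_class,
                  xci_status = genes$xci_status,
                  enrichment = c(1, 2, 3, 4))
  b <- a; b$enrichment <- a$enrichment          # b = a -> slope 1
  sc <- scatter_summary(a, b, genes)
  expect_equal(sc$trends$slope, c(1, 1), tolerance = 1e-12)
  expect_equal(sc$trends$intercept, c(0, 0), tolerance = 1e-12)
  b2 <- a; b2$enrichment <- 0.85 * a$enrichment # b = 0.85 a -> slope 0.85
  sc2 <- scatter_summary(a, b2, genes)
  expect_equal(sc2$trends$slope, c(0.85, 0.85), tolerance = 1e-12)
  expect_true("xci_status" %in% names(sc$table))
  expect_equal(sc$table$xci_status[sc$table$gene_id == "gX2"], "escape")
})
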
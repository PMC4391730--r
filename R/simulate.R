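#' Simulation configuration for a toy F1-hybrid dataset
#'
#' Defaults describe the system the package targets: two haplotypes differing
#' by frequent SNPs (about 1 per 75 bp, the middle of the observed 1 per
#' 50-100 bp density), 100-nt single-end reads, 50x coverage, and a skewed
#' allelic read origin on the X (inactive-X fraction 0.16 of reads).
#'
#' @param genome_length bases per chromosome.
#' @param n_chromosomes chromosome count; the last one is named "chrX" and
#'   flagged as the X, the others "chr1", "chr2", ...
#' @param snp_rate per-base probability of a strain SNP, in (0, 1).
#' @param read_length read length in bases.
#' @param coverage mean reads per base.
#' @param allelic_skew default fraction of reads drawn from the alternate
#'   haplotype, in `[0, 1]`; per-chromosome values can override it in
#'   [simulate_reads()].
#' @param error_rate per-base substitution error probability.
#' @param mapq MAPQ written on simulated alignments (simulator bypasses an
#'   aligner; emitted records are at the true coordinates).
#' @param seed RNG seed; identical config + seed gives identical output.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(genome_length = 100000L, n_chromosomes = 2L,
                       snp_rate = 1 / 75, read_length = 100L, coverage = 50,
                       allelic_skew = 0.16, error_rate = 0.001, mapq = 60L,
                       seed = 1L) {
  .stopifnot_scalar(genome_length, "genome_length", 1)
  .stopifnot_scalar(n_chromosomes, "n_chromosomes", 1)
  if (snp_rate < 0 || snp_rate >= 1) stop("snp_rate must be in [0, 1)")
  .stopifnot_scalar(read_length, "read_length", 1)
  .stopifnot_scalar(coverage, "coverage", 0)
  .stopifnot_scalar(allelic_skew, "allelic_skew", 0, 1)
  .stopifnot_scalar(error_rate, "error_rate", 0, 1)
  cfg <- list(genome_length = as.integer(genome_length),
              n_chromosomes = as.integer(n_chromosomes),
              snp_rate = snp_rate, read_length = as.integer(read_length),
              coverage = coverage, allelic_skew = allelic_skew,
              error_rate = error_rate, mapq = as.integer(mapq),
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

.sim_chrom_names <- function(config) {
  n <- config$n_chromosomes
  if (n == 1L) "chrX" else c(paste0("chr", seq_len(n - 1L)), "chrX")
}

#' Simulate a two-haplotype genome and its SNP table
#'
#' Draws a random reference genome and places strain SNPs as a per-base
#' Bernoulli process at `snp_rate`; each SNP's alternate allele is drawn
#' uniformly from the three non-reference bases, so ref != alt at every SNP.
#'
#' @param config a [sim_config()].
#' @return list with `reference` (`DNAStringSet`, last chromosome "chrX") and
#'   `snps` (a [snp_table()]).
#' @export
simulate_genome_pair <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$genome_length < 1L) stop("zero-length genome")
  .with_seed(config$seed, {
    bases <- c("A", "C", "G", "T")
    chroms <- .sim_chrom_names(config)
    seqs <- character(length(chroms))
    snp <- vector("list", length(chroms))
    for (i in seq_along(chroms)) {
      b <- sample.int(4L, config$genome_length, replace = TRUE)
      seqs[i] <- paste(bases[b], collapse = "")
      at <- which(stats::runif(config$genome_length) < config$snp_rate)
      if (length(at)) {
        alt <- (b[at] - 1L + sample.int(3L, length(at), replace = TRUE)) %% 4L + 1L
        snp[[i]] <- data.frame(chrom = chroms[i], pos = at,
                               ref = bases[b[at]], alt = bases[alt])
      }
    }
    snps <- do.call(rbind, snp)
    if (is.null(snps)) snps <- snp_table()
    else snps <- snp_table(snps$chrom, snps$pos, snps$ref, snps$alt)
    list(reference = Biostrings::DNAStringSet(stats::setNames(seqs, chroms)),
         snps = snps)
  })
}

#' Simulate single-end reads from a two-haplotype genome with ground truth
#'
#' For each chromosome, `round(coverage * length / read_length)` reads are
#' drawn at uniform positions; each read originates from the alternate
#' haplotype with the chromosome's skew probability (e.g. the Xi fraction of
#' reads on the X) and from the reference haplotype otherwise. Per-base
#' substitution errors are applied at `error_rate`. Alignment records are
#' emitted directly at the true coordinates with the configured MAPQ — the
#' off-the-shelf alignment step is deliberately bypassed.
#'
#' @param genomes list with `reference` and optionally `pseudo`
#'   (`DNAStringSet`s); `pseudo` is built from `snps` when absent.
#' @param snps a [snp_table()].
#' @param config a [sim_config()].
#' @param region_skew named numeric vector mapping chromosome name to the
#'   alternate-haplotype read fraction; chromosomes not named fall back to
#'   `config$allelic_skew`. A single unnamed value applies to all.
#' @return list with `alignments` (an [alignments()] table carrying
#'   `true_hap`/`true_pos`) and `truth` (data.frame read_id, chrom, true_pos,
#'   true_hap).
#' @export
simulate_reads <- function(genomes, snps, config,
                           region_skew = config$allelic_skew) {
  stopifnot(inherits(config, "sim_config"))
  ref <- .as_dnastringset(genomes$reference)
  pseudo <- if (!is.null(genomes$pseudo)) .as_dnastringset(genomes$pseudo)
            else build_pseudogenome(ref, snps)
  lens <- .chrom_lengths(ref)
  if (config$read_length > min(lens))
    stop("read_length exceeds chromosome length")
  skew_of <- function(chr) {
    if (is.null(names(region_skew))) region_skew[1]
    else if (chr %in% names(region_skew)) unname(region_skew[chr])
    else config$allelic_skew
  }
  .with_seed(config$seed + 1L, {
    out <- vector("list", length(lens))
    for (i in seq_along(lens)) {
      chr <- names(lens)[i]
      n <- round(config$coverage * lens[[i]] / config$read_length)
      if (n == 0) next
      start <- sample.int(lens[[i]] - config$read_length + 1L, n,
                          replace = TRUE)
      hap <- ifelse(stats::runif(n) < skew_of(chr), "A", "R")
      src_ref <- as.character(ref[[chr]])
      src_alt <- as.character(pseudo[[chr]])
      sq <- ifelse(hap == "A",
                   substring(src_alt, start, start + config$read_length - 1L),
                   substring(src_ref, start, start + config$read_length - 1L))
      if (config$error_rate > 0) {
        nerr <- stats::rbinom(n, config$read_length, config$error_rate)
        for (j in which(nerr > 0L)) {
          at <- sample.int(config$read_length, nerr[j])
          old <- substring(sq[j], at, at)
          new <- vapply(old, function(b)
            sample(setdiff(c("A", "C", "G", "T"), b), 1L), "")
          for (k in seq_along(at))
            substr(sq[j], at[k], at[k]) <- new[k]
        }
      }
      out[[i]] <- alignments(
        qname = sprintf("%s_r%07d", chr, seq_len(n)),
        chrom = chr, pos = start, seq = sq, mapq = config$mapq,
        cigar = paste0(config$read_length, "M"),
        true_hap = hap, true_pos = start)
    }
    aln <- do.call(rbind, out)
    truth <- data.frame(read_id = aln$qname, chrom = aln$chrom,
                        true_pos = aln$true_pos, true_hap = aln$true_hap,
                        stringsAsFactors = FALSE)
    list(alignments = aln, truth = truth)
  })
}

#' Simulate a gene model set on toy chromosomes
#'
#' Places non-overlapping single- or two-exon genes with alternating strand at
#' regular spacing: X-linked genes on "chrX", autosomal genes spread over the
#' remaining chromosomes. A configurable fraction of X genes is labeled as
#' escaping X inactivation.
#'
#' @param n_x,n_autosome gene counts per class.
#' @param gene_length,spacing bases; spacing is TSS-to-TSS and must exceed
#'   `gene_length` plus twice any metagene span you intend to profile if you
#'   want non-overlapping windows.
#' @param escape_fraction fraction of X genes labeled "escape".
#' @param n_exons exons per gene (1 or 2; 2 leaves a central intron).
#' @param seed RNG seed for strand and escape label assignment.
#' @return a [gene_model()] table.
#' @export
simulate_genes <- function(n_x = 30L, n_autosome = 70L, gene_length = 2000L,
                           spacing = 10000L, escape_fraction = 0.1,
                           n_exons = 2L, seed = 1L) {
  .with_seed(seed, {
    mk <- function(n, chrom, class, prefix) {
      if (n == 0L) return(NULL)
      tss_plus <- spacing * (seq_len(n) - 1L) + spacing %/% 2L
      strand <- rep_len(c("+", "-"), n)
      tss <- ifelse(strand == "+", tss_plus, tss_plus + gene_length - 1L)
      g_start <- tss_plus
      g_end <- tss_plus + gene_length - 1L
      if (n_exons >= 2L) {
        third <- gene_length %/% 3L
        es <- Map(function(s, e) c(s, e - third + 1L), g_start, g_end)
        ee <- Map(function(s, e) c(s + third - 1L, e), g_start, g_end)
      } else {
        es <- as.list(g_start); ee <- as.list(g_end)
      }
      status <- if (class == "X")
        ifelse(stats::runif(n) < escape_fraction, "escape", "subject")
      else "unknown"
      gene_model(sprintf("%s%04d", prefix, seq_len(n)), chrom, strand,
                 tss, es, ee, chrom_class = class, xci_status = status)
    }
    g <- rbind(mk(n_autosome, "chr1", "autosome", "auto"),
               mk(n_x, "chrX", "X", "xg"))
    class(g) <- c("gene_model", "data.frame")
    g
  })
}

#' Simulate TSS-anchored enrichment signal for control and knockdown tracks
#'
#' Emits piecewise-constant log2(ChIP/input)-style signal in fixed bins
#' spanning `span` bases either side of each TSS. Per-gene enrichment levels
#' are lognormal around a class baseline (X-linked genes higher than
#' autosomal, matching a repressive mark concentrated on the Xi; escape genes
#' near zero); in the knockdown track the X-gene mean is reduced by
#' `x_effect` while autosomal genes are unchanged in expectation. The two
#' conditions are drawn independently (two independent experiments), so with
#' `x_effect = 0` they are exchangeable.
#'
#' @param genes a [gene_model()] table.
#' @param x_effect fractional reduction of X-gene enrichment in the knockdown,
#'   in `[0, 1]`.
#' @param seed RNG seed.
#' @param span,bin signal extent around each TSS and bin width, bases.
#' @param base_x,base_autosome class baseline enrichment (log2-ratio units).
#' @param gene_sd lognormal sd of per-gene levels (log scale).
#' @param noise_sd per-bin additive Gaussian noise sd.
#' @return list of two signal data.frames (`control`, `knockdown`) with
#'   columns chrom, start (0-based), end, score.
#' @export
simulate_enrichment <- function(genes, x_effect = 0.16, seed = 1L,
                                span = 3000L, bin = 100L, base_x = 1.2,
                                base_autosome = 0.5, gene_sd = 0.3,
                                noise_sd = 0.15) {
  .stopifnot_scalar(x_effect, "x_effect", 0, 1)
  .with_seed(seed, {
    one_track <- function(x_mult) {
      base <- ifelse(genes$chrom_class == "X",
                     ifelse(genes$xci_status == "escape", 0.05,
                            base_x * x_mult),
                     base_autosome)
      level <- base * stats::rlnorm(nrow(genes), -gene_sd^2 / 2, gene_sd)
      n_bins <- 2L * span %/% bin
      lo <- genes$tss - span          # 0-based window start
      starts <- rep(lo, each = n_bins) + bin * (seq_len(n_bins) - 1L)
      data.frame(chrom = rep(genes$chrom, each = n_bins),
                 start = starts, end = starts + bin,
                 score = rep(level, each = n_bins) +
                   stats::rnorm(n_bins * nrow(genes), 0, noise_sd),
                 stringsAsFactors = FALSE)
    }
    list(control = one_track(1), knockdown = one_track(1 - x_effect))
  })
}

#' Simulate per-nucleus FISH association outcomes
#'
#' Each nucleus carries `ploidy` alleles; each allele associates with the
#' nucleolus independently with probability `p_allele`. The fraction of nuclei
#' with at least one associated allele therefore converges to
#' `1 - (1 - p_allele)^ploidy`.
#'
#' @param n_nuclei nuclei scored.
#' @param p_allele per-allele association probability.
#' @param ploidy alleles per nucleus.
#' @param seed RNG seed.
#' @return data.frame with nucleus_id, one `allele_<i>` logical column per
#'   allele, `n_associated` and `associated` (>= 1 allele).
#' @export
simulate_fish <- function(n_nuclei, p_allele, ploidy = 2L, seed = 1L) {
  .stopifnot_scalar(p_allele, "p_allele", 0, 1)
  .with_seed(seed, {
    m <- matrix(stats::runif(n_nuclei * ploidy) < p_allele, ncol = ploidy)
    df <- data.frame(nucleus_id = seq_len(n_nuclei))
    for (i in seq_len(ploidy)) df[[paste0("allele_", i)]] <- m[, i]
    df$n_associated <- rowSums(m)
    df$associated <- df$n_associated >= 1L
    df
  })
}
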
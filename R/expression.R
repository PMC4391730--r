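#' Gene-level allelic SNP-read counts, RPKM and SRPM
#'
#' A classified read contributes to a gene when its 5'-most aligned base lies
#' in one of the gene's exons — or anywhere in the gene body for genes listed
#' in `include_introns` (used for loci whose informative reads are largely
#' intronic, e.g. a macrosatellite lncRNA). REF/ALT categories are mapped to
#' Xi/Xa through `xi_allele`, a required declaration of which haplotype
#' carries the inactive X in the system at hand (it differs between cell
#' lines and tissues).
#'
#' Units: `rpkm` is total exonic reads (all categories) per kb of exon per
#' million mapped library reads; `srpm_xi`/`srpm_xa` are SNP reads per 10
#' million mapped library reads. The denominator is the library's total
#' mapped read count, not the allelic subset.
#'
#' @param classified a [classify_reads()] table.
#' @param genes a [gene_model()] table.
#' @param xi_allele "REF" or "ALT": the haplotype on the inactive X.
#' @param total_mapped total mapped reads in the library (defaults to
#'   `nrow(classified)`, appropriate when the table is the whole library).
#' @param include_introns gene ids whose whole gene body is counted.
#' @param condition label stored on the result.
#' @return data.frame of class `allelic_expression`: gene_id, chrom_class,
#'   xci_status, snp_reads_xi, snp_reads_xa, total_reads, rpkm, srpm_xi,
#'   srpm_xa, condition; attributes `total_mapped`, `xi_allele`,
#'   `n_multi_gene_reads` (reads assigned to >1 overlapping gene, each copy
#'   counted and flagged).
#' @export
count_gene_alleles <- function(classified, genes, xi_allele = c("ALT", "REF"),
                               total_mapped = nrow(classified),
                               include_introns = character(),
                               condition = "condition") {
  xi_allele <- match.arg(xi_allele)
  if (total_mapped <= 0) stop("total_mapped must be positive")
  point <- ifelse(classified$strand == "-",
                  classified$start + classified$length - 1L,
                  classified$start)
  pgr <- GenomicRanges::GRanges(classified$chrom,
                                IRanges::IRanges(point + 1L, width = 1L))
  use_body <- genes$gene_id %in% include_introns
  exon_part <- .exon_granges(genes[!use_body, , drop = FALSE])
  body_part <- .body_granges(genes[use_body, , drop = FALSE])
  # remap subset-local gene indices back to rows of `genes`
  exon_part$gene <- which(!use_body)[exon_part$gene]
  body_part$gene <- which(use_body)[body_part$gene]
  target <- c(exon_part, body_part)
  ov <- GenomicRanges::findOverlaps(pgr, target)
  ri <- S4Vectors::queryHits(ov)
  gi <- target$gene[S4Vectors::subjectHits(ov)]
  keep <- !duplicated(cbind(ri, gi))   # read hits several exons of one gene
  ri <- ri[keep]; gi <- gi[keep]
  n_multi <- sum(table(ri) > 1L)
  ng <- nrow(genes)
  cat_ <- classified$category[ri]
  n_ref <- tabulate(gi[cat_ == "REF"], nbins = ng)
  n_alt <- tabulate(gi[cat_ == "ALT"], nbins = ng)
  n_tot <- tabulate(gi, nbins = ng)
  exon_kb <- vapply(seq_len(ng), function(i)
    sum(genes$exon_end[[i]] - genes$exon_start[[i]] + 1L), 0L) / 1000
  xi <- if (xi_allele == "ALT") n_alt else n_ref
  xa <- if (xi_allele == "ALT") n_ref else n_alt
  out <- data.frame(gene_id = genes$gene_id, chrom_class = genes$chrom_class,
                    xci_status = genes$xci_status,
                    snp_reads_xi = xi, snp_reads_xa = xa, total_reads = n_tot,
                    rpkm = n_tot / exon_kb / (total_mapped / 1e6),
                    srpm_xi = xi * 1e7 / total_mapped,
                    srpm_xa = xa * 1e7 / total_mapped,
                    condition = condition, stringsAsFactors = FALSE)
  attr(out, "total_mapped") <- total_mapped
  attr(out, "xi_allele") <- xi_allele
  attr(out, "n_multi_gene_reads") <- n_multi
  class(out) <- c("allelic_expression", "data.frame")
  out
}

#' Sequencing-depth adjustment between two libraries
#'
#' The adjustment factor is the ratio of total mapped reads,
#' `mapped_b / mapped_a`; counts of library b are divided by it so the two
#' conditions are comparable (e.g. 23.7 M / 22.3 M = 1.06 to 2 d.p.).
#'
#' @param mapped_a,mapped_b total mapped reads of conditions a and b.
#' @return list of class `depth_adjustment` with `mapped_a`, `mapped_b`,
#'   `factor`.
#' @export
depth_adjustment <- function(mapped_a, mapped_b) {
  if (mapped_a <= 0 || mapped_b <= 0) stop("library sizes must be positive")
  structure(list(mapped_a = mapped_a, mapped_b = mapped_b,
                 factor = mapped_b / mapped_a),
            class = "depth_adjustment")
}

#' Apply a depth adjustment to condition-b counts
#'
#' Divides the SNP-read counts of library b by the depth factor; raw counts
#' are preserved in `snp_reads_xi_raw`/`snp_reads_xa_raw`.
#'
#' @param expr_b an [count_gene_alleles()] result for condition b.
#' @param adjustment a [depth_adjustment()].
#' @return `expr_b` with adjusted counts.
#' @export
adjust_depth <- function(expr_b, adjustment) {
  if (!inherits(adjustment, "depth_adjustment") || adjustment$factor <= 0)
    stop("invalid depth adjustment (factor must be > 0)")
  expr_b$snp_reads_xi_raw <- expr_b$snp_reads_xi
  expr_b$snp_reads_xa_raw <- expr_b$snp_reads_xa
  expr_b$total_reads_raw <- expr_b$total_reads
  expr_b$snp_reads_xi <- expr_b$snp_reads_xi / adjustment$factor
  expr_b$snp_reads_xa <- expr_b$snp_reads_xa / adjustment$factor
  expr_b$total_reads <- expr_b$total_reads / adjustment$factor
  attr(expr_b, "depth_factor") <- adjustment$factor
  expr_b
}

#' Xi/Xa expression ratio of one gene
#'
#' @param expr a one-row [count_gene_alleles()] result (or any list with
#'   `snp_reads_xi` and `snp_reads_xa`).
#' @return `snp_reads_xi / snp_reads_xa`; 0 when xi = 0 and xa > 0; `NA` with
#'   a warning when xa = 0 (undefined).
#' @export
xi_xa_ratio <- function(expr) {
  xi <- expr$snp_reads_xi; xa <- expr$snp_reads_xa
  if (length(xi) != 1L) stop("xi_xa_ratio expects a single gene")
  if (xa == 0) {
    warning("Xa count is zero: Xi/Xa ratio undefined")
    return(NA_real_)
  }
  xi / xa
}

#' Nearest-integer percentage of regulated genes
#'
#' @param n_changed,n_total counts.
#' @return `round(100 * n_changed / n_total)`.
#' @export
regulation_fractions <- function(n_changed, n_total) {
  if (any(n_total <= 0)) stop("n_total must be positive")
  round(100 * n_changed / n_total)
}

#' Classify genes into expression / regulation categories between conditions
#'
#' Implements the expressed-gene filter and the Xi-informative subsets:
#' `expressed` are genes with RPKM at or above `rpkm_min` in either condition;
#' among expressed X-linked genes, `subset1` are those with Xi SRPM at or
#' above `srpm_min` in condition a, condition b, or both (raw counts by
#' default) and `subset2` is the remainder. Per-gene fold changes (b/a on
#' adjusted total counts, with a 0.5-count continuity offset for zero counts)
#' are called up/down at each cutoff only when the pluggable significance
#' test rejects. The default test is a documented stand-in for the original
#' pipeline's differential-expression model: a two-sided binomial test of the
#' raw b count against the raw a count given the library-depth ratio,
#' Benjamini-Hochberg corrected at `alpha`.
#'
#' @param expr_a,expr_b [count_gene_alleles()] results (b usually
#'   depth-adjusted via [adjust_depth()]).
#' @param rpkm_min expressed-gene threshold (default 1 RPKM).
#' @param srpm_min Xi-informative threshold (default 5 SRPM).
#' @param cutoffs fold-change cutoffs (default 1.25, 1.5, 2).
#' @param alpha BH-adjusted significance level.
#' @param sig_test optional function(raw_a, raw_b, depth_factor) returning
#'   per-gene p-values, replacing the stand-in.
#' @param srpm_on_adjusted apply the SRPM threshold to adjusted rather than
#'   raw counts.
#' @return list with `calls` (per gene and cutoff: fold_change, direction,
#'   significant, group) and `summary` (per group and cutoff: n, n_up,
#'   n_down, pct_up, pct_down).
#' @export
classify_genes <- function(expr_a, expr_b, rpkm_min = 1, srpm_min = 5,
                           cutoffs = c(1.25, 1.5, 2), alpha = 0.05,
                           sig_test = NULL, srpm_on_adjusted = FALSE) {
  stopifnot(identical(expr_a$gene_id, expr_b$gene_id))
  expressed <- expr_a$rpkm >= rpkm_min | expr_b$rpkm >= rpkm_min
  if (!any(expressed)) stop("no expressed genes at rpkm_min = ", rpkm_min)
  a <- expr_a[expressed, , drop = FALSE]
  b <- expr_b[expressed, , drop = FALSE]
  tm_a <- attr(expr_a, "total_mapped")
  srpm_b <- if (srpm_on_adjusted)
    b$snp_reads_xi * 1e7 / attr(expr_b, "total_mapped")
  else (if (!is.null(b$snp_reads_xi_raw)) b$snp_reads_xi_raw
        else b$snp_reads_xi) * 1e7 / attr(expr_b, "total_mapped")
  xi_informative <- a$srpm_xi >= srpm_min | srpm_b >= srpm_min
  group <- ifelse(a$chrom_class == "X",
                  ifelse(xi_informative, "X_subset1", "X_subset2"),
                  "autosome")
  raw_a <- if (!is.null(a$total_reads_raw)) a$total_reads_raw else a$total_reads
  raw_b <- if (!is.null(b$total_reads_raw)) b$total_reads_raw else b$total_reads
  factor <- if (!is.null(attr(expr_b, "depth_factor")))
    attr(expr_b, "depth_factor") else 1
  fold <- (b$total_reads + 0.5 / factor) / (a$total_reads + 0.5)
  pvals <- if (is.null(sig_test)) {
    p_b <- factor / (1 + factor)   # P(read from b) under no change
    vapply(seq_along(raw_a), function(i) {
      n <- raw_a[i] + raw_b[i]
      if (n == 0) 1 else stats::binom.test(round(raw_b[i]), round(n),
                                           p = p_b)$p.value
    }, 0)
  } else sig_test(raw_a, raw_b, factor)
  padj <- stats::p.adjust(pvals, method = "BH")
  significant <- padj < alpha
  calls <- do.call(rbind, lapply(cutoffs, function(ct) {
    direction <- rep.int("unchanged", nrow(a))
    direction[significant & fold > ct] <- "up"
    direction[significant & fold < 1 / ct] <- "down"
    data.frame(gene_id = a$gene_id, group = group, cutoff = ct,
               fold_change = fold, p_adj = padj, significant = significant,
               direction = direction, stringsAsFactors = FALSE)
  }))
  summary <- do.call(rbind, lapply(split(calls, list(calls$group,
                                                     calls$cutoff)),
                                   function(d) {
    data.frame(group = d$group[1], cutoff = d$cutoff[1], n = nrow(d),
               n_up = sum(d$direction == "up"),
               n_down = sum(d$direction == "down"),
               pct_up = regulation_fractions(sum(d$direction == "up"), nrow(d)),
               pct_down = regulation_fractions(sum(d$direction == "down"),
                                               nrow(d)))
  }))
  rownames(summary) <- NULL
  list(calls = calls, summary = summary)
}
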
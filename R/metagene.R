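# Coverage-weighted means of piecewise-constant signal over query windows.
# windows: GRanges; returns numeric vector (NA where uncovered).
.window_means <- function(signal, windows) {
  sgr <- GenomicRanges::GRanges(signal$chrom,
                                IRanges::IRanges(signal$start + 1L,
                                                 signal$end))
  ov <- GenomicRanges::findOverlaps(windows, sgr)
  qi <- S4Vectors::queryHits(ov)
  si <- S4Vectors::subjectHits(ov)
  w <- GenomicRanges::width(IRanges::pintersect(
    GenomicRanges::ranges(windows)[qi], GenomicRanges::ranges(sgr)[si]))
  num <- rep.int(0, length(windows))
  den <- rep.int(0, length(windows))
  agg <- rowsum(cbind(w * signal$score[si], w), qi)
  idx <- as.integer(rownames(agg))
  num[idx] <- agg[, 1]
  den[idx] <- agg[, 2]
  ifelse(den > 0, num / den, NA_real_)
}

# strand-oriented genomic interval for a TSS-relative window [lo, hi)
# (offsets in transcription direction; returns 1-based closed GRanges)
.tss_window_granges <- function(genes, lo, hi) {
  plus <- genes$strand == "+"
  start1 <- ifelse(plus, genes$tss + lo, genes$tss - hi + 1L)
  end1 <- ifelse(plus, genes$tss + hi - 1L, genes$tss - lo)
  GenomicRanges::GRanges(genes$chrom, IRanges::IRanges(start1, end1))
}

#' TSS-anchored metagene enrichment profile (end-analysis)
#'
#' For each offset on a regular grid spanning `span` bases either side of the
#' TSS, computes the coverage-weighted mean signal within a sliding window
#' centred on the offset — in TSS-relative, strand-oriented coordinates, so
#' "+1 kb" is transcriptionally downstream for both strands — then averages
#' over genes (each covered gene contributes equally). Defaults follow the
#' denser-array dialect: 500-bp window every 100 bp; `dialect = "agilent"`
#' selects 600/200.
#'
#' @param signal signal data.frame (chrom, start, end, score), piecewise
#'   constant; e.g. from [read_bedgraph()] or [simulate_enrichment()].
#' @param genes a [gene_model()] table.
#' @param window,step,span grid geometry in bases (window >= step,
#'   span >= window/2).
#' @param dialect "nimblegen" (500/100) or "agilent" (600/200); overridden by
#'   explicit `window`/`step`.
#' @return data.frame of class `metagene_profile`: offset, mean_enrichment,
#'   n_genes.
#' @export
metagene_profile <- function(signal, genes, window = NULL, step = NULL,
                             span = 3000L,
                             dialect = c("nimblegen", "agilent")) {
  dialect <- match.arg(dialect)
  if (is.null(window)) window <- if (dialect == "nimblegen") 500L else 600L
  if (is.null(step)) step <- if (dialect == "nimblegen") 100L else 200L
  if (window < step) stop("window must be >= step")
  if (span < window) stop("span must be >= window")
  offsets <- seq.int(-span, span, by = step)
  n_genes_tot <- nrow(genes)
  if (!n_genes_tot) stop("no genes supplied")
  half <- window %/% 2L
  means <- matrix(NA_real_, nrow = n_genes_tot, ncol = length(offsets))
  for (j in seq_along(offsets)) {
    wgr <- .tss_window_granges(genes, offsets[j] - half, offsets[j] + half)
    means[, j] <- .window_means(signal, wgr)
  }
  n_contrib <- as.integer(colSums(!is.na(means)))
  if (all(n_contrib == 0L))
    stop("no gene has signal within the profiled span")
  out <- data.frame(offset = offsets,
                    mean_enrichment = colMeans(means, na.rm = TRUE),
                    n_genes = n_contrib)
  out$mean_enrichment[n_contrib == 0L] <- NA_real_
  class(out) <- c("metagene_profile", "data.frame")
  out
}

#' Per-gene enrichment over the gene body 1-2 kb downstream of the TSS
#'
#' Coverage-weighted mean of the signal over the strand-aware TSS-relative
#' interval `[+1000, +2000)` for each gene. Genes whose interval has no signal
#' coverage are omitted (not zero-filled); the omitted count is available as
#' attribute `n_uncovered`. Intervals truncated by a chromosome edge are
#' averaged over the covered portion.
#'
#' @param signal signal data.frame.
#' @param genes a [gene_model()] table.
#' @param from,to interval bounds in TSS-relative bases (half-open).
#' @return data.frame of class `enrichment_summary`: gene_id, chrom_class,
#'   xci_status, enrichment.
#' @export
gene_body_enrichment <- function(signal, genes, from = 1000L, to = 2000L) {
  wgr <- .tss_window_granges(genes, from, to)
  val <- .window_means(signal, wgr)
  covered <- !is.na(val)
  out <- data.frame(gene_id = genes$gene_id[covered],
                    chrom_class = genes$chrom_class[covered],
                    xci_status = genes$xci_status[covered],
                    enrichment = val[covered], stringsAsFactors = FALSE)
  attr(out, "n_uncovered") <- sum(!covered)
  class(out) <- c("enrichment_summary", "data.frame")
  out
}

#' Distribution-shift test between two per-gene enrichment summaries
#'
#' Two-sample Kolmogorov-Smirnov test on the per-gene enrichment values of
#' conditions a and b, plus the percent change of the mean,
#' `100 * (mean_b - mean_a) / mean_a`.
#'
#' @param summary_a,summary_b [gene_body_enrichment()] results (or numeric
#'   vectors of per-gene values).
#' @return list: `ks_statistic`, `p_value`, `percent_change`, `mean_a`,
#'   `mean_b`, `n_a`, `n_b`.
#' @export
shift_test <- function(summary_a, summary_b) {
  va <- if (is.data.frame(summary_a)) summary_a$enrichment else summary_a
  vb <- if (is.data.frame(summary_b)) summary_b$enrichment else summary_b
  if (length(va) < 3L || length(vb) < 3L)
    stop("need at least 3 genes per condition")
  ks <- suppressWarnings(stats::ks.test(va, vb))
  list(ks_statistic = unname(ks$statistic), p_value = ks$p.value,
       percent_change = 100 * (mean(vb) - mean(va)) / mean(va),
       mean_a = mean(va), mean_b = mean(vb),
       n_a = length(va), n_b = length(vb))
}

#' Paired per-gene enrichment scatter with per-class trend lines
#'
#' Matches the two summaries by gene id and fits an ordinary least-squares
#' trend `b ~ a` within each chromosome class.
#'
#' @param summary_a,summary_b [gene_body_enrichment()] results.
#' @param genes a [gene_model()] table (source of class / XCI labels).
#' @return list with `table` (gene_id, a, b, chrom_class, xci_status) and
#'   `trends` (chrom_class, slope, intercept, n).
#' @export
scatter_summary <- function(summary_a, summary_b, genes) {
  common <- intersect(summary_a$gene_id, summary_b$gene_id)
  gi <- match(common, genes$gene_id)
  tab <- data.frame(gene_id = common,
                    a = summary_a$enrichment[match(common, summary_a$gene_id)],
                    b = summary_b$enrichment[match(common, summary_b$gene_id)],
                    chrom_class = genes$chrom_class[gi],
                    xci_status = genes$xci_status[gi],
                    stringsAsFactors = FALSE)
  trends <- do.call(rbind, lapply(split(tab, tab$chrom_class), function(d) {
    fit <- stats::lm(b ~ a, data = d)
    data.frame(chrom_class = d$chrom_class[1],
               slope = unname(stats::coef(fit)[2]),
               intercept = unname(stats::coef(fit)[1]), n = nrow(d))
  }))
  rownames(trends) <- NULL
  list(table = tab, trends = trends)
}
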
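#' Construct a gene model table
#'
#' Gene models drive metagene profiling and gene-level allelic counting. Each
#' gene has a 1-based TSS, a strand, a sorted non-overlapping exon list and a
#' chromosome class (`"X"` or `"autosome"`); `xci_status` records whether an
#' X-linked gene is subject to X inactivation, escapes it, or is unassessed.
#'
#' @param gene_id unique identifiers.
#' @param chrom,strand,tss chromosome, "+"/"-", and 1-based TSS position.
#' @param exon_start,exon_end list columns (one integer vector per gene) of
#'   1-based inclusive exon bounds; scalars are accepted for single-exon genes.
#' @param chrom_class "X" or "autosome".
#' @param xci_status "subject", "escape" or "unknown".
#' @return data.frame of class `gene_model`.
#' @export
gene_model <- function(gene_id, chrom, strand, tss, exon_start, exon_end,
                       chrom_class = "autosome", xci_status = "unknown") {
  if (anyDuplicated(gene_id)) stop("gene_id values must be unique")
  if (!all(strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (!all(chrom_class %in% c("X", "autosome")))
    stop("chrom_class must be 'X' or 'autosome'")
  if (!all(xci_status %in% c("subject", "escape", "unknown")))
    stop("xci_status must be subject/escape/unknown")
  if (!is.list(exon_start)) exon_start <- as.list(exon_start)
  if (!is.list(exon_end)) exon_end <- as.list(exon_end)
  for (i in seq_along(exon_start)) {
    s <- as.integer(exon_start[[i]]); e <- as.integer(exon_end[[i]])
    if (length(s) != length(e) || any(e < s))
      stop("malformed exons for gene ", gene_id[i])
    o <- order(s)
    s <- s[o]; e <- e[o]
    if (length(s) > 1L && any(s[-1L] <= e[-length(e)]))
      stop("overlapping exons for gene ", gene_id[i])
    exon_start[[i]] <- s; exon_end[[i]] <- e
  }
  df <- data.frame(gene_id = as.character(gene_id),
                   chrom = as.character(chrom),
                   strand = as.character(strand),
                   tss = as.integer(tss),
                   chrom_class = rep_len(chrom_class, length(gene_id)),
                   xci_status = rep_len(xci_status, length(gene_id)),
                   stringsAsFactors = FALSE)
  df$exon_start <- exon_start
  df$exon_end <- exon_end
  class(df) <- c("gene_model", "data.frame")
  df
}

#' Read / write gene models as a tab-separated table
#'
#' Columns: gene_id, chrom, strand, tss, chrom_class, xci_status, exon_starts,
#' exon_ends — the last two comma-separated 1-based inclusive coordinates
#' (BED12-style block lists, but 1-based like the rest of the text interfaces).
#'
#' @param path file path.
#' @return `read_gene_models`: a [gene_model()] table.
#' @export
read_gene_models <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  split_ints <- function(x) lapply(strsplit(as.character(x), ","),
                                   function(v) as.integer(v))
  gene_model(df$gene_id, df$chrom, df$strand, df$tss,
             split_ints(df$exon_starts), split_ints(df$exon_ends),
             df$chrom_class, df$xci_status)
}

#' @rdname read_gene_models
#' @param genes a [gene_model()] table.
#' @export
write_gene_models <- function(genes, path) {
  out <- data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
                    strand = genes$strand, tss = genes$tss,
                    chrom_class = genes$chrom_class,
                    xci_status = genes$xci_status,
                    exon_starts = vapply(genes$exon_start, paste, "",
                                         collapse = ","),
                    exon_ends = vapply(genes$exon_end, paste, "",
                                       collapse = ","))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# exon GRanges with gene index in mcols
.exon_granges <- function(genes) {
  n <- lengths(genes$exon_start)
  GenomicRanges::GRanges(rep.int(genes$chrom, n),
                         IRanges::IRanges(unlist(genes$exon_start),
                                          unlist(genes$exon_end)),
                         gene = rep.int(seq_len(nrow(genes)), n))
}

# gene body (first exon start .. last exon end) GRanges
.body_granges <- function(genes) {
  GenomicRanges::GRanges(genes$chrom,
                         IRanges::IRanges(vapply(genes$exon_start, min, 0L),
                                          vapply(genes$exon_end, max, 0L)),
                         gene = seq_len(nrow(genes)))
}
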
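#' Construct an alignment table
#'
#' Alignments are carried through the package as a plain `data.frame` with the
#' essential SAM fields: `qname`, `flag`, `chrom`, `pos` (1-based leftmost),
#' `mapq`, `cigar`, `seq`, plus optional simulator truth columns `true_hap`
#' ("R"/"A") and `true_pos`. [write_sam()]/[read_sam()] round-trip this table
#' through SAM (truth in optional `XH`/`XP` tags).
#'
#' @param qname read identifiers.
#' @param flag SAM bit flags (default 0: mapped, forward, primary).
#' @param chrom,pos,mapq,cigar,seq usual SAM columns.
#' @param true_hap,true_pos optional simulator ground truth.
#' @return data.frame of class `xallele_alignments`.
#' @export
alignments <- function(qname, chrom, pos, seq, flag = 0L, mapq = 60L,
                       cigar = paste0(nchar(seq), "M"),
                       true_hap = NULL, true_pos = NULL) {
  df <- data.frame(qname = as.character(qname), flag = as.integer(flag),
                   chrom = as.character(chrom), pos = as.integer(pos),
                   mapq = as.integer(mapq), cigar = as.character(cigar),
                   seq = toupper(as.character(seq)), stringsAsFactors = FALSE)
  if (!is.null(true_hap)) df$true_hap <- as.character(true_hap)
  if (!is.null(true_pos)) df$true_pos <- as.integer(true_pos)
  class(df) <- c("xallele_alignments", "data.frame")
  df
}

#' Write alignments to a SAM file
#'
#' Emits a minimal valid single-end SAM with `@SQ` header lines. Simulator
#' truth columns, when present, are written as optional tags `XH:A` (true
#' haplotype, R or A) and `XP:i` (true 1-based position).
#'
#' @param aln an [alignments()] table.
#' @param chrom_lengths named integer vector of chromosome lengths (or a
#'   `DNAStringSet`, from which lengths are taken).
#' @param path output `.sam` path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(aln, chrom_lengths, path) {
  if (!is.null(dim(chrom_lengths)) || !is.numeric(chrom_lengths))
    chrom_lengths <- .chrom_lengths(chrom_lengths)
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lengths),
                   as.integer(chrom_lengths)))
  qual <- strrep("I", nchar(aln$seq))
  opt <- rep.int("", nrow(aln))
  if (!is.null(aln$true_hap))
    opt <- paste0(opt, "\tXH:A:", aln$true_hap)
  if (!is.null(aln$true_pos))
    opt <- paste0(opt, "\tXP:i:", aln$true_pos)
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s%s",
                  aln$qname, aln$flag, aln$chrom, aln$pos, aln$mapq,
                  aln$cigar, aln$seq, qual, opt)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a SAM/BAM file into an alignment table
#'
#' SAM input is converted with [Rsamtools::asBam()] (htslib) and scanned; the
#' optional truth tags written by [write_sam()] are recovered when present.
#'
#' @param path `.sam` or `.bam` path.
#' @return An [alignments()] table.
#' @export
read_sam <- function(path) {
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile()
    bam <- Rsamtools::asBam(path, dest, overwrite = TRUE, indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq"),
    tag = c("XH", "XP"))
  x <- Rsamtools::scanBam(bam, param = p)[[1]]
  df <- data.frame(qname = x$qname, flag = as.integer(x$flag),
                   chrom = as.character(x$rname), pos = as.integer(x$pos),
                   mapq = as.integer(x$mapq), cigar = as.character(x$cigar),
                   seq = as.character(x$seq), stringsAsFactors = FALSE)
  if (!is.null(x$tag$XH) && !all(is.na(x$tag$XH))) df$true_hap <- x$tag$XH
  if (!is.null(x$tag$XP) && !all(is.na(x$tag$XP))) df$true_pos <- x$tag$XP
  class(df) <- c("xallele_alignments", "data.frame")
  df
}

# Decompose CIGARs into match blocks (M/=/X): one row per block with the
# 1-based reference start, width, and the 1-based query offset of the block's
# first base. Soft-clipped and inserted bases advance the query only; D/N
# advance the reference only. Hard clips and padding consume neither.
.cigar_blocks <- function(cigar, pos) {
  toks <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))
  n_ops <- lengths(toks)
  op_len <- as.integer(sub("[A-Z=]$", "", unlist(toks)))
  op <- sub("^\\d+", "", unlist(toks))
  idx <- rep.int(seq_along(cigar), n_ops)
  ref_consume <- op %in% c("M", "D", "N", "=", "X")
  qry_consume <- op %in% c("M", "I", "S", "=", "X")
  # cumulative offsets within each alignment, before the op
  csum <- function(x) {
    cs <- cumsum(x)
    first <- !duplicated(idx)
    cs - rep.int(cs[first] - x[first], n_ops)  # per-group cumsum
  }
  ref_off <- csum(op_len * ref_consume) - op_len * ref_consume
  qry_off <- csum(op_len * qry_consume) - op_len * qry_consume
  keep <- op %in% c("M", "=", "X")
  data.frame(aln = idx[keep],
             ref_start = pos[idx[keep]] + ref_off[keep],
             width = op_len[keep],
             q_start = qry_off[keep] + 1L)
}

# reference span (bases consumed on the reference) per CIGAR
.ref_span <- function(cigar) {
  toks <- regmatches(cigar, gregexpr("\\d+[MDN=X]", cigar))
  vapply(toks, function(t) sum(as.integer(sub("[A-Z=]$", "", t))), 0L)
}
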
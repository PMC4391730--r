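#' Construct a strain SNP table
#'
#' A SNP table catalogs the single-nucleotide differences between the two
#' haplotypes of an F1 hybrid: the reference strain base (`ref`) and the
#' alternate strain base (`alt`) at each 1-based position. It is the basis of
#' every allelic assignment in the package.
#'
#' @param chrom character vector of chromosome names.
#' @param pos integer vector of 1-based positions.
#' @param ref,alt single-base alleles (A/C/G/T); `ref` must differ from `alt`.
#' @return A `data.frame` of class `snp_table` sorted by (chrom, pos).
#' @examples
#' snp_table(c("chr1", "chr1"), c(10L, 55L), c("A", "C"), c("G", "T"))
#' @export
snp_table <- function(chrom = character(), pos = integer(),
                      ref = character(), alt = character()) {
  ref <- toupper(as.character(ref))
  alt <- toupper(as.character(alt))
  tab <- data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                    ref = ref, alt = alt, stringsAsFactors = FALSE)
  if (nrow(tab)) {
    bad <- !ref %in% c("A", "C", "G", "T") | !alt %in% c("A", "C", "G", "T")
    if (any(bad))
      stop("single-nucleotide A/C/G/T alleles required (rows ",
           paste(which(bad), collapse = ","), ")")
    if (any(ref == alt))
      stop("ref allele equals alt allele at rows ",
           paste(which(ref == alt), collapse = ","))
    dup <- duplicated(tab[c("chrom", "pos")])
    if (any(dup))
      stop("duplicate SNP positions: ",
           paste(tab$chrom[dup], tab$pos[dup], sep = ":", collapse = ", "))
    tab <- tab[order(tab$chrom, tab$pos), , drop = FALSE]
    rownames(tab) <- NULL
  }
  class(tab) <- c("snp_table", "data.frame")
  tab
}

#' Read a SNP table from a tab-separated or minimal VCF file
#'
#' Accepts either a headered TSV with columns chrom/pos/ref/alt or a VCF, from
#' which only CHROM, POS, REF and ALT are used. Multi-nucleotide records are
#' rejected, not dropped: the coordinate-shared pseudo-genome model admits
#' only substitutions.
#'
#' @param path file path.
#' @return A [snp_table()].
#' @export
read_snp_table <- function(path) {
  first <- readLines(path, n = 50L)
  if (any(startsWith(first, "##fileformat=VCF")) ||
      any(startsWith(first, "#CHROM"))) {
    lines <- readLines(path)
    lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
    if (!length(lines)) return(snp_table())
    f <- strsplit(lines, "\t", fixed = TRUE)
    tab <- data.frame(chrom = vapply(f, `[[`, "", 1L),
                      pos = as.integer(vapply(f, `[[`, "", 2L)),
                      ref = vapply(f, `[[`, "", 4L),
                      alt = vapply(f, `[[`, "", 5L),
                      stringsAsFactors = FALSE)
  } else {
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             colClasses = "character")
    names(tab) <- tolower(names(tab))
    need <- c("chrom", "pos", "ref", "alt")
    if (!all(need %in% names(tab)))
      stop("SNP table needs columns chrom/pos/ref/alt")
    tab <- tab[need]
    tab$pos <- as.integer(tab$pos)
  }
  mnv <- nchar(tab$ref) != 1L | nchar(tab$alt) != 1L
  if (any(mnv))
    stop(sum(mnv), " non-SNV record(s) (indel or MNV); only single-base ",
         "substitutions are supported")
  snp_table(tab$chrom, tab$pos, tab$ref, tab$alt)
}

#' Write a SNP table as tab-separated chrom/pos/ref/alt
#'
#' @param snps a [snp_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_snp_table <- function(snps, path) {
  utils::write.table(as.data.frame(snps), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# GRanges of width-1 SNP loci, metadata ref/alt; shared by classifiers
.snp_granges <- function(snps) {
  GenomicRanges::GRanges(snps$chrom,
                         IRanges::IRanges(snps$pos, width = 1L),
                         ref = snps$ref, alt = snps$alt)
}
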
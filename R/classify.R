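#' Alignment retention policy
#'
#' Mirrors the filtering used for allele-specific analyses: only reads mapped
#' uniquely and with MAPQ at or above the threshold (default 30) are kept.
#' Genes with known cross-mapping trouble (e.g. a gene whose exons share high
#' sequence similarity with another region, depressing MAPQ) can be exempted
#' via `low_mapq_whitelist`: reads overlapping a whitelisted gene's exons are
#' retained regardless of MAPQ.
#'
#' @param mapq_min minimum MAPQ (default 30).
#' @param require_unique drop reads that carry secondary or supplementary
#'   records anywhere in the stream.
#' @param low_mapq_whitelist character vector of gene ids exempt from the
#'   MAPQ floor.
#' @return list of class `filter_policy`.
#' @export
filter_policy <- function(mapq_min = 30L, require_unique = TRUE,
                          low_mapq_whitelist = character()) {
  if (mapq_min < 0) stop("mapq_min must be >= 0")
  structure(list(mapq_min = as.integer(mapq_min),
                 require_unique = isTRUE(require_unique),
                 low_mapq_whitelist = as.character(low_mapq_whitelist)),
            class = "filter_policy")
}

.FLAG_UNMAPPED <- 0x4L
.FLAG_REVERSE <- 0x10L
.FLAG_SECONDARY <- 0x100L
.FLAG_SUPPLEMENTARY <- 0x800L

#' Filter alignments by mapping quality and uniqueness
#'
#' Retains mapped, primary, non-supplementary records with
#' `mapq >= policy$mapq_min`. Reads below the floor are rescued when their
#' aligned span overlaps an exon of a whitelisted gene. When
#' `policy$require_unique`, any read name carrying secondary/supplementary
#' records is dropped entirely.
#'
#' @param aln an [alignments()] table.
#' @param policy a [filter_policy()].
#' @param genes a [gene_model()] table; required when the whitelist is
#'   non-empty.
#' @return the retained subset of `aln`.
#' @export
filter_alignments <- function(aln, policy = filter_policy(), genes = NULL) {
  mapped <- bitwAnd(aln$flag, .FLAG_UNMAPPED) == 0L
  primary <- bitwAnd(aln$flag, .FLAG_SECONDARY) == 0L &
    bitwAnd(aln$flag, .FLAG_SUPPLEMENTARY) == 0L
  keep <- mapped & primary
  if (policy$require_unique) {
    multi <- unique(aln$qname[mapped & !primary])
    keep <- keep & !aln$qname %in% multi
  }
  qual_ok <- aln$mapq >= policy$mapq_min
  if (length(policy$low_mapq_whitelist)) {
    if (is.null(genes)) stop("whitelist given but no gene models supplied")
    wl <- genes[genes$gene_id %in% policy$low_mapq_whitelist, , drop = FALSE]
    if (nrow(wl)) {
      span <- .ref_span(aln$cigar)
      rgr <- GenomicRanges::GRanges(aln$chrom,
                                    IRanges::IRanges(aln$pos,
                                                     width = pmax(span, 1L)))
      hit <- GenomicRanges::countOverlaps(rgr, .exon_granges(wl)) > 0L
      qual_ok <- qual_ok | hit
    }
  }
  out <- aln[keep & qual_ok, , drop = FALSE]
  if (!nrow(out) && nrow(aln) && !any(mapped))
    warning("no mapped alignments in input; returning empty set")
  rownames(out) <- NULL
  out
}

#' Classify reads into reference, alternate and ambiguous allele categories
#'
#' Every SNP falling inside an aligned (CIGAR M/=/X) block of a read is
#' evaluated at the corresponding read base: a base equal to the reference
#' allele counts towards `n_ref_snps`, equal to the alternate allele towards
#' `n_alt_snps`, and equal to neither towards `n_other_snps` (uninformative —
#' usually a sequencing error). Soft-clipped bases never count. The category
#' is `REF` iff the read carries at least one reference-allele base and no
#' alternate-allele base, `ALT` for the mirror case, and `AMBIGUOUS`
#' otherwise (no SNPs covered, both alleles seen, or only uninformative
#' bases). Reads on chromosomes absent from the SNP table are `AMBIGUOUS`.
#'
#' @param aln an [alignments()] table (typically already filtered).
#' @param snps a [snp_table()].
#' @return data.frame of class `classified_reads`: read_id, chrom, start
#'   (0-based), length (reference span), strand, mapq, genome_of_alignment,
#'   n_ref_snps, n_alt_snps, n_other_snps, category.
#' @export
classify_reads <- function(aln, snps) {
  n <- nrow(aln)
  nref <- nalt <- noth <- integer(n)
  if (n && nrow(snps)) {
    blocks <- .cigar_blocks(aln$cigar, aln$pos)
    bgr <- GenomicRanges::GRanges(aln$chrom[blocks$aln],
                                  IRanges::IRanges(blocks$ref_start,
                                                   width = blocks$width))
    sgr <- .snp_granges(snps)
    ov <- GenomicRanges::findOverlaps(sgr, bgr, ignore.strand = TRUE)
    if (length(ov)) {
      si <- S4Vectors::queryHits(ov)
      bi <- S4Vectors::subjectHits(ov)
      ai <- blocks$aln[bi]
      qpos <- blocks$q_start[bi] + (snps$pos[si] - blocks$ref_start[bi])
      base <- toupper(substring(aln$seq[ai], qpos, qpos))
      is_ref <- base == snps$ref[si]
      is_alt <- base == snps$alt[si]
      nref <- tabulate(ai[is_ref], nbins = n)
      nalt <- tabulate(ai[is_alt], nbins = n)
      noth <- tabulate(ai[!is_ref & !is_alt], nbins = n)
    }
  }
  category <- rep.int("AMBIGUOUS", n)
  category[nref >= 1L & nalt == 0L] <- "REF"
  category[nalt >= 1L & nref == 0L] <- "ALT"
  out <- data.frame(
    read_id = aln$qname, chrom = aln$chrom, start = aln$pos - 1L,
    length = .ref_span(aln$cigar),
    strand = ifelse(bitwAnd(aln$flag, .FLAG_REVERSE) != 0L, "-", "+"),
    mapq = aln$mapq,
    genome_of_alignment = if (!is.null(aln$genome_of_alignment))
      aln$genome_of_alignment else "reference",
    n_ref_snps = nref, n_alt_snps = nalt, n_other_snps = noth,
    category = category, stringsAsFactors = FALSE)
  class(out) <- c("classified_reads", "data.frame")
  out
}

#' Reconcile dual alignments against reference and pseudo-genome
#'
#' Reads are aligned separately to the reference and to the pseudo-genome; a
#' read passing the filter in at least one genome is kept exactly once. When
#' it passes in both, the higher-MAPQ alignment wins; at equal MAPQ the two
#' coordinates must agree (the genomes are coordinate-identical) and the
#' reference record is used. Equal-MAPQ coordinate disagreements are dropped
#' and reported.
#'
#' @param aln_ref,aln_pseudo [alignments()] tables from the two genomes.
#' @param policy a [filter_policy()].
#' @param genes optional gene models for the whitelist.
#' @return list with `alignments` (one record per read, with a
#'   `genome_of_alignment` column) and `discordant` (dropped reads report).
#' @export
reconcile_dual_alignments <- function(aln_ref, aln_pseudo,
                                      policy = filter_policy(),
                                      genes = NULL) {
  a <- filter_alignments(aln_ref, policy, genes)
  b <- filter_alignments(aln_pseudo, policy, genes)
  a$genome_of_alignment <- rep.int("reference", nrow(a))
  b$genome_of_alignment <- rep.int("pseudo", nrow(b))
  both <- intersect(a$qname, b$qname)
  only_a <- a[!a$qname %in% both, , drop = FALSE]
  only_b <- b[!b$qname %in% both, , drop = FALSE]
  discordant <- NULL
  pick <- NULL
  if (length(both)) {
    ia <- a[match(both, a$qname), , drop = FALSE]
    ib <- b[match(both, b$qname), , drop = FALSE]
    use_b <- ib$mapq > ia$mapq
    tie <- ib$mapq == ia$mapq
    agree <- ia$chrom == ib$chrom & ia$pos == ib$pos
    bad <- tie & !agree
    if (any(bad))
      discordant <- data.frame(qname = both[bad],
                               chrom_ref = ia$chrom[bad], pos_ref = ia$pos[bad],
                               chrom_pseudo = ib$chrom[bad],
                               pos_pseudo = ib$pos[bad],
                               reason = "equal_mapq_coordinate_disagreement",
                               stringsAsFactors = FALSE)
    keep_a <- ia[!use_b & !bad, , drop = FALSE]
    keep_b <- ib[use_b, , drop = FALSE]
    pick <- rbind(keep_a, keep_b)
  }
  out <- rbind(only_a, only_b, pick)
  rownames(out) <- NULL
  if (is.null(discordant))
    discordant <- data.frame(qname = character(), chrom_ref = character(),
                             pos_ref = integer(), chrom_pseudo = character(),
                             pos_pseudo = integer(), reason = character())
  list(alignments = out, discordant = discordant)
}

#' Write a classified-read summary table
#'
#' @param classified a [classify_reads()] result.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_classified_tsv <- function(classified, path) {
  utils::write.table(as.data.frame(classified), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
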
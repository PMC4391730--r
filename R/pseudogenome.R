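#' Build the alternate-strain pseudo-genome
#'
#' Substitutes the alternate allele at every SNP position into the reference
#' sequences, producing a genome that is coordinate-identical to the reference
#' (substitution-only model: any interval has the same coordinates in both
#' genomes). Non-SNP positions are untouched and keep the reference case;
#' substituted bases are emitted uppercase.
#'
#' @param reference a [Biostrings::DNAStringSet] (or named character vector) of
#'   reference chromosomes.
#' @param snps a [snp_table()]; `ref` alleles are validated against the
#'   reference (case-insensitively) and any mismatch is an error naming the
#'   offending chrom/pos.
#' @return A `DNAStringSet` of the same names and lengths as `reference`.
#' @examples
#' ref <- Biostrings::DNAStringSet(c(chr1 = "ACGT"))
#' build_pseudogenome(ref, snp_table("chr1", 2L, "C", "T"))  # ATGT
#' @export
build_pseudogenome <- function(reference, snps) {
  reference <- .as_dnastringset(reference)
  rep <- validate_snps(reference, snps)
  if (nrow(rep))
    stop("SNP table invalid against reference:\n  ",
         paste(rep$message, collapse = "\n  "))
  out <- reference
  snps$alt <- toupper(snps$alt)
  for (chr in unique(snps$chrom)) {
    rows <- snps[snps$chrom == chr, , drop = FALSE]
    rows <- rows[order(rows$pos), , drop = FALSE]
    at <- rep.int(FALSE, length(reference[[chr]]))
    at[rows$pos] <- TRUE
    out[[chr]] <- Biostrings::replaceLetterAt(reference[[chr]], at,
                                              paste(rows$alt, collapse = ""))
  }
  out
}

#' Validate a SNP table against a reference genome
#'
#' Report-based checker: returns one row per invariant violation (unknown
#' chromosome, position beyond chromosome end, duplicate position, ref = alt,
#' non-ACGT allele, reference-base mismatch). Base comparison is
#' case-insensitive. An empty report means the table is valid.
#'
#' @param reference a `DNAStringSet` or named character vector.
#' @param snps a data.frame with columns chrom/pos/ref/alt (a [snp_table()]
#'   already guarantees several invariants; raw data.frames are accepted so
#'   broken input can be diagnosed).
#' @return data.frame with columns chrom, pos, problem, message.
#' @export
validate_snps <- function(reference, snps) {
  reference <- .as_dnastringset(reference)
  rep <- data.frame(chrom = character(), pos = integer(),
                    problem = character(), message = character())
  flag <- function(i, problem, detail) {
    data.frame(chrom = snps$chrom[i], pos = snps$pos[i], problem = problem,
               message = sprintf("%s:%d %s", snps$chrom[i], snps$pos[i], detail))
  }
  if (!nrow(snps)) return(rep)
  snps <- as.data.frame(snps)
  snps$ref <- toupper(snps$ref); snps$alt <- toupper(snps$alt)
  out <- list()
  dup <- duplicated(snps[c("chrom", "pos")])
  if (any(dup)) out$dup <- flag(which(dup), "duplicate", "duplicate position")
  badal <- !snps$ref %in% c("A", "C", "G", "T") |
    !snps$alt %in% c("A", "C", "G", "T")
  if (any(badal)) out$allele <- flag(which(badal), "bad_allele",
                                     "allele not a single A/C/G/T base")
  same <- !badal & snps$ref == snps$alt
  if (any(same)) out$same <- flag(which(same), "ref_equals_alt",
                                  "ref and alt alleles identical")
  unk <- !snps$chrom %in% names(reference)
  if (any(unk)) out$unk <- flag(which(unk), "unknown_chrom",
                                "chromosome absent from reference")
  lens <- stats::setNames(Biostrings::width(reference), names(reference))
  oob <- !unk & (snps$pos < 1L | snps$pos > lens[snps$chrom])
  if (any(oob)) out$oob <- flag(which(oob), "out_of_bounds",
                                "position beyond chromosome end")
  ok <- which(!unk & !oob & !badal)
  if (length(ok)) {
    base <- character(length(ok))
    for (chr in unique(snps$chrom[ok])) {
      sel <- snps$chrom[ok] == chr
      base[sel] <- as.character(Biostrings::extractAt(
        reference[[chr]], IRanges::IRanges(snps$pos[ok][sel], width = 1L)))
    }
    base <- toupper(base)
    mis <- base != snps$ref[ok]
    if (any(mis))
      out$mis <- flag(ok[mis], "ref_mismatch",
                      sprintf("ref allele %s does not match reference base %s",
                              snps$ref[ok][mis], base[mis]))
  }
  if (length(out)) rep <- do.call(rbind, unname(out))
  rownames(rep) <- NULL
  rep
}

.as_dnastringset <- function(x) {
  if (methods::is(x, "DNAStringSet")) return(x)
  if (is.character(x)) {
    if (is.null(names(x))) stop("sequences must be named")
    return(Biostrings::DNAStringSet(x))
  }
  stop("expected a DNAStringSet or named character vector")
}

#' Read / write genomes as FASTA
#'
#' Thin wrappers around [Biostrings::readDNAStringSet()] and
#' [Biostrings::writeXStringSet()], kept so pipeline stages share one entry
#' point.
#' @param path FASTA path.
#' @return `read_genome_fasta`: a `DNAStringSet`.
#' @export
read_genome_fasta <- function(path) Biostrings::readDNAStringSet(path)

#' @rdname read_genome_fasta
#' @param genome a `DNAStringSet`.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(.as_dnastringset(genome), path)
  invisible(path)
}
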
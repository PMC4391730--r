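#' Define an amplicon spanning a strain SNP
#'
#' @param sequence amplicon sequence carrying the reference allele.
#' @param snp_offset 0-based offset of the SNP within the amplicon.
#' @param ref_allele,alt_allele the two alleles; `sequence[snp_offset]` must
#'   equal `ref_allele`.
#' @return list of class `amplicon`.
#' @export
amplicon <- function(sequence, snp_offset, ref_allele, alt_allele) {
  sequence <- toupper(sequence)
  ref_allele <- toupper(ref_allele); alt_allele <- toupper(alt_allele)
  if (grepl("[^ACGTRYSWKMBDHVN]", sequence))
    stop("amplicon contains characters outside the IUPAC alphabet")
  if (snp_offset < 0 || snp_offset >= nchar(sequence))
    stop("snp_offset outside amplicon")
  if (substring(sequence, snp_offset + 1L, snp_offset + 1L) != ref_allele)
    stop("sequence does not carry ref_allele at snp_offset")
  if (ref_allele == alt_allele) stop("ref and alt alleles identical")
  structure(list(sequence = sequence, snp_offset = as.integer(snp_offset),
                 ref_allele = ref_allele, alt_allele = alt_allele),
            class = "amplicon")
}

#' Define a restriction enzyme
#'
#' @param name enzyme name.
#' @param recognition_site IUPAC recognition sequence (length >= 4).
#' @param cut_offset bases of the site left of the cut on the recognition
#'   strand (e.g. 1 for BglII A^GATCT).
#' @return list of class `enzyme`.
#' @export
enzyme <- function(name, recognition_site, cut_offset) {
  recognition_site <- toupper(recognition_site)
  if (nchar(recognition_site) < 4L) stop("recognition site must be >= 4 bases")
  if (cut_offset < 0 || cut_offset > nchar(recognition_site))
    stop("cut_offset outside recognition site")
  structure(list(name = name, recognition_site = recognition_site,
                 cut_offset = as.integer(cut_offset)), class = "enzyme")
}

# all double-strand cut positions (0-based, cut after that many bases of the
# top strand) for one sequence; both orientations scanned, IUPAC-aware,
# overlapping occurrences each cut, duplicate positions collapsed
.cut_positions <- function(seqchar, enz) {
  s <- Biostrings::DNAString(seqchar)
  L <- nchar(enz$recognition_site)
  site <- Biostrings::DNAString(enz$recognition_site)
  rc <- Biostrings::reverseComplement(site)
  fwd <- Biostrings::start(Biostrings::matchPattern(site, s, fixed = FALSE))
  cuts <- fwd - 1L + enz$cut_offset
  if (as.character(rc) != as.character(site)) {
    rev <- Biostrings::start(Biostrings::matchPattern(rc, s, fixed = FALSE))
    cuts <- c(cuts, rev - 1L + (L - enz$cut_offset))
  }
  sort(unique(cuts[cuts > 0L & cuts < nchar(seqchar)]))
}

#' In-silico allele-discriminating restriction digest
#'
#' Scans both allelic versions of the amplicon (reference allele vs the SNP
#' substituted alternate allele) for the enzyme's recognition site on both
#' strands with IUPAC degeneracy, and returns the fragment lengths between
#' cut positions. The enzyme discriminates the alleles when the number of cut
#' sites differs — the situation exploited by RFLP genotyping, where the SNP
#' creates or destroys a site in one allele only.
#'
#' @param amp an [amplicon()].
#' @param enz an [enzyme()].
#' @return list of class `digest_result`: `fragments_ref`, `fragments_alt`
#'   (lengths summing to the amplicon length), `cuts_ref`, `cuts_alt`
#'   (0-based cut positions) and `discriminating`.
#' @export
digest <- function(amp, enz) {
  stopifnot(inherits(amp, "amplicon"), inherits(enz, "enzyme"))
  seq_ref <- amp$sequence
  seq_alt <- seq_ref
  substr(seq_alt, amp$snp_offset + 1L, amp$snp_offset + 1L) <- amp$alt_allele
  cuts_ref <- .cut_positions(seq_ref, enz)
  cuts_alt <- .cut_positions(seq_alt, enz)
  len <- nchar(seq_ref)
  structure(list(
    fragments_ref = diff(c(0L, cuts_ref, len)),
    fragments_alt = diff(c(0L, cuts_alt, len)),
    cuts_ref = cuts_ref, cuts_alt = cuts_alt,
    discriminating = length(cuts_ref) != length(cuts_alt)),
    class = "digest_result")
}

#' Screen an enzyme panel for allele discrimination
#'
#' Digests the amplicon with every enzyme and returns the discriminating
#' ones, ranked by a gel-resolvability proxy: the smallest absolute length
#' difference between a fragment unique to one allele's digest and the
#' nearest fragment of the other digest (larger = easier to resolve).
#'
#' @param amp an [amplicon()].
#' @param enzymes list of [enzyme()] objects (or a data.frame with columns
#'   name, recognition_site, cut_offset).
#' @return data.frame (possibly empty): name, n_cuts_ref, n_cuts_alt,
#'   min_fragment_diff, ordered by decreasing resolvability.
#' @export
screen_enzymes <- function(amp, enzymes) {
  if (is.data.frame(enzymes))
    enzymes <- Map(enzyme, enzymes$name, enzymes$recognition_site,
                   enzymes$cut_offset)
  if (!length(enzymes)) stop("empty enzyme set")
  rows <- lapply(enzymes, function(e) {
    d <- digest(amp, e)
    if (!d$discriminating) return(NULL)
    fr <- sort(d$fragments_ref); fa <- sort(d$fragments_alt)
    uniq <- c(setdiff(fr, fa), setdiff(fa, fr))
    other <- c(fa, fr)
    gap <- function(f) {
      d <- abs(other - f); d <- d[d > 0]
      if (length(d)) min(d) else 0
    }
    score <- if (length(uniq)) min(vapply(uniq, gap, 0)) else 0
    data.frame(name = e$name, n_cuts_ref = length(d$cuts_ref),
               n_cuts_alt = length(d$cuts_alt), min_fragment_diff = score,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows))
    return(data.frame(name = character(), n_cuts_ref = integer(),
                      n_cuts_alt = integer(), min_fragment_diff = numeric()))
  out <- do.call(rbind, rows)
  out <- out[order(-out$min_fragment_diff), , drop = FALSE]
  rownames(out) <- NULL
  out
}
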
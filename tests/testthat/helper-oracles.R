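# Independent oracles used by the test suite. These deliberately avoid the
# package's own code paths (Biostrings matching, GRanges overlap) so that
# agreement is evidence, not tautology.

IUPAC <- list(A = "A", C = "C", G = "G", T = "T",
              R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
              W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
              B = c("C", "G", "T"), D = c("A", "G", "T"),
              H = c("A", "C", "T"), V = c("A", "C", "G"),
              N = c("A", "C", "G", "T"))

COMP <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
          W = "W", K = "M", M = "K", B = "V", D = "H", H = "D", V = "B",
          N = "N")

bf_revcomp <- function(x)
  paste(rev(COMP[strsplit(toupper(x), "")[[1]]]), collapse = "")

# brute force: does IUPAC pattern match seq at 1-based position p?
bf_match_at <- function(seqchars, patchars, p) {
  for (k in seq_along(patchars)) {
    if (!seqchars[p + k - 1L] %in% IUPAC[[patchars[k]]]) return(FALSE)
  }
  TRUE
}

# brute-force double-strand cut positions (0-based), same geometry contract
# as the package: forward match at p cuts after cut_offset bases; a match of
# the reverse-complemented site at q cuts after (L - cut_offset) bases
bf_cut_positions <- function(seqchar, site, cut_offset) {
  sc <- strsplit(toupper(seqchar), "")[[1]]
  L <- nchar(site)
  cuts <- integer()
  pats <- list(list(p = strsplit(toupper(site), "")[[1]], off = cut_offset))
  rc <- bf_revcomp(site)
  if (rc != toupper(site))
    pats <- c(pats, list(list(p = strsplit(rc, "")[[1]], off = L - cut_offset)))
  for (pat in pats) {
    for (p in seq_len(length(sc) - L + 1L)) {
      if (bf_match_at(sc, pat$p, p)) cuts <- c(cuts, p - 1L + pat$off)
    }
  }
  sort(unique(cuts[cuts > 0L & cuts < length(sc)]))
}

# brute-force two-sample KS statistic from empirical CDFs evaluated at every
# data point
bf_ks_stat <- function(a, b) {
  grid <- sort(unique(c(a, b)))
  Fa <- vapply(grid, function(t) mean(a <= t), 0)
  Fb <- vapply(grid, function(t) mean(b <= t), 0)
  max(abs(Fa - Fb))
}

# random DNA string
rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

# tiny deterministic gene set: one plus- and one minus-strand gene per class
toy_genes <- function() {
  gene_model(gene_id = c("gA", "gB", "gX1", "gX2"),
             chrom = c("chr1", "chr1", "chrX", "chrX"),
             strand = c("+", "-", "+", "-"),
             tss = c(10000L, 30000L, 10000L, 30000L),
             exon_start = list(c(10000L, 11500L), c(28001L, 29500L),
                               10000L, 28001L),
             exon_end = list(c(11000L, 12000L), c(28900L, 30000L),
                             12000L, 30000L),
             chrom_class = c("autosome", "autosome", "X", "X"),
             xci_status = c("unknown", "unknown", "subject", "escape"))
}

# constant-score signal covering [0, n) on the given chromosomes
const_signal <- function(chroms, n, score = 1) {
  data.frame(chrom = chroms, start = 0L, end = as.integer(n), score = score)
}
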
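#' Count classified reads into fixed-width windows
#'
#' Tiles each chromosome with half-open windows `[0, w), [w, 2w), ...` and
#' assigns every read to exactly one window — the one containing its 5'-most
#' aligned base (alignment start for plus-strand reads, alignment end minus
#' one for minus-strand reads). Point assignment keeps totals conserved and
#' makes window refinement exact: halving the width and re-summing adjacent
#' pairs reproduces the coarser track.
#'
#' @param classified a [classify_reads()] table.
#' @param window_size window width in bases (default 100).
#' @param chrom_lengths named vector of chromosome lengths (or a
#'   `DNAStringSet`); chromosomes present in `classified` must be covered.
#' @return data.frame of class `window_track`: chrom, start, end (0-based
#'   half-open), total, ref, alt, ambiguous; attribute `window_size`.
#' @export
count_windows <- function(classified, window_size = 100L, chrom_lengths) {
  if (window_size < 1L) stop("window_size must be >= 1")
  if (!is.null(dim(chrom_lengths)) || !is.numeric(chrom_lengths))
    chrom_lengths <- .chrom_lengths(chrom_lengths)
  missing_chr <- setdiff(unique(classified$chrom), names(chrom_lengths))
  if (length(missing_chr))
    stop("chromosome length unknown for: ", paste(missing_chr, collapse = ", "))
  point <- ifelse(classified$strand == "-",
                  classified$start + classified$length - 1L,
                  classified$start)
  if (any(point < 0L) ||
      any(point >= chrom_lengths[classified$chrom]))
    stop("read 5' base beyond chromosome end: corrupt input")
  per_chrom <- lapply(names(chrom_lengths), function(chr) {
    nwin <- as.integer(ceiling(chrom_lengths[[chr]] / window_size))
    sel <- classified$chrom == chr
    widx <- point[sel] %/% window_size + 1L
    cat_ <- classified$category[sel]
    tally <- function(which_cat)
      tabulate(widx[cat_ %in% which_cat], nbins = nwin)
    starts <- window_size * (seq_len(nwin) - 1L)
    data.frame(chrom = chr, start = starts,
               end = pmin(starts + window_size, chrom_lengths[[chr]]),
               total = tabulate(widx, nbins = nwin),
               ref = tally("REF"), alt = tally("ALT"),
               ambiguous = tally("AMBIGUOUS"), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, per_chrom)
  rownames(out) <- NULL
  attr(out, "window_size") <- as.integer(window_size)
  class(out) <- c("window_track", "data.frame")
  out
}

#' Export window-track layers as bedGraph
#'
#' Writes one UCSC bedGraph per requested layer containing the non-zero
#' windows (0-based half-open coordinates), optionally with a `track` header
#' line.
#'
#' @param track a [count_windows()] result.
#' @param which layers to export, subset of total/ref/alt/ambiguous.
#' @param dir output directory; files are named `<prefix>_<layer>.bedGraph`.
#' @param prefix file-name prefix.
#' @param trackline write a `track type=bedGraph` header line.
#' @return named character vector of file paths.
#' @export
export_tracks <- function(track, which = c("total", "ref", "alt"),
                          dir = ".", prefix = "track", trackline = FALSE) {
  which <- match.arg(which, c("total", "ref", "alt", "ambiguous"),
                     several.ok = TRUE)
  paths <- character(0)
  for (layer in which) {
    path <- file.path(dir, sprintf("%s_%s.bedGraph", prefix, layer))
    keep <- track[[layer]] != 0L
    lines <- sprintf("%s\t%d\t%d\t%d", track$chrom[keep], track$start[keep],
                     track$end[keep], track[[layer]][keep])
    if (trackline)
      lines <- c(sprintf("track type=bedGraph name=\"%s_%s\"", prefix, layer),
                 lines)
    writeLines(lines, path)
    paths[layer] <- path
  }
  paths
}

#' Read / write a piecewise-constant signal track as bedGraph
#'
#' Signal (e.g. log2 ChIP/input enrichment) is carried as a data.frame with
#' columns chrom, start (0-based), end, score. I/O goes through
#' [rtracklayer::import.bedGraph()] / [rtracklayer::export.bedGraph()].
#'
#' @param path bedGraph path.
#' @return `read_bedgraph`: signal data.frame.
#' @export
read_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             score = gr$score, stringsAsFactors = FALSE)
}

#' @rdname read_bedgraph
#' @param signal signal data.frame (chrom, start, end, score).
#' @export
write_bedgraph <- function(signal, path) {
  gr <- GenomicRanges::GRanges(signal$chrom,
                               IRanges::IRanges(signal$start + 1L,
                                                signal$end),
                               score = signal$score)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}
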
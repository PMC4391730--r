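# Evaluate expr with a temporarily fixed RNG state; restores the caller's seed
.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

.stopifnot_scalar <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi)
    stop(name, " must be a single number in [", lo, ", ", hi, "]")
  invisible(x)
}

# chromosome lengths as a named integer vector from a DNAStringSet / named vec
.chrom_lengths <- function(genome) {
  g <- .as_dnastringset(genome)
  stats::setNames(Biostrings::width(g), names(g))
}
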
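#' Nucleolar-association frequency with a Wilson confidence interval
#'
#' Fraction of scored nuclei with at least one FISH signal adjacent to the
#' nucleolus surface. Experiments scoring fewer than 100 nuclei trigger a
#' warning (the conventional scoring floor).
#'
#' @param n_associated nuclei with >= 1 associated signal.
#' @param n_nuclei nuclei scored (> 0).
#' @param conf confidence level (default 0.95).
#' @return list: `frequency`, `lower`, `upper`, `n_associated`, `n_nuclei`.
#' @export
assoc_frequency <- function(n_associated, n_nuclei, conf = 0.95) {
  if (n_nuclei <= 0) stop("n_nuclei must be positive")
  if (n_associated < 0 || n_associated > n_nuclei)
    stop("n_associated must be in [0, n_nuclei]")
  if (n_nuclei < 100) warning("fewer than 100 nuclei scored")
  p <- n_associated / n_nuclei
  z <- stats::qnorm(1 - (1 - conf) / 2)
  denom <- 1 + z^2 / n_nuclei
  centre <- (p + z^2 / (2 * n_nuclei)) / denom
  half <- z * sqrt(p * (1 - p) / n_nuclei + z^2 / (4 * n_nuclei^2)) / denom
  list(frequency = p, lower = max(0, centre - half),
       upper = min(1, centre + half),
       n_associated = n_associated, n_nuclei = n_nuclei)
}

#' Diploid background model for nucleolar association
#'
#' Extrapolates a per-allele association probability (estimated in
#' haploid-equivalent male nuclei, which carry one X) to a cell with `ploidy`
#' alleles. Two expectations for "at least one associated signal" are
#' reported: the additive approximation `ploidy * p` (capped at 1) and the
#' exact independent-allele complement `1 - (1 - p)^ploidy`. The additive
#' form overestimates the exact one by `p^2` at ploidy 2.
#'
#' @param p_allele per-allele association probability, in `[0, 1]`.
#' @param ploidy allele count per nucleus.
#' @return list of class `background_model`: `p_allele`, `ploidy`,
#'   `expected_additive`, `expected_exact`.
#' @export
assoc_background <- function(p_allele, ploidy = 2L) {
  .stopifnot_scalar(p_allele, "p_allele", 0, 1)
  structure(list(p_allele = p_allele, ploidy = as.integer(ploidy),
                 expected_additive = min(1, ploidy * p_allele),
                 expected_exact = 1 - (1 - p_allele)^ploidy),
            class = "background_model")
}

#' Compare association frequencies between experiments
#'
#' Three methods covering the comparisons used for FISH scoring data:
#' `two_proportion_chi2` — Pearson chi-square (no continuity correction) on
#' the 2x2 table of associated / non-associated counts; `unpaired_t` —
#' two-tailed unpaired Student t-test on replicate-level frequencies;
#' `one_sample_t` — two-tailed one-sample t-test of replicate ratios against
#' `mu` (default 1, no change). All are symmetric in their two arguments.
#'
#' @param a,b for the chi-square: length-2 vectors `c(n_associated,
#'   n_nuclei)`; for the unpaired t: numeric replicate vectors; for the
#'   one-sample t: `a` = replicate ratios, `b` ignored.
#' @param method one of the three above.
#' @param mu null value for the one-sample t-test.
#' @return list: `method`, `statistic`, `p_value`, `df` (NA for chi-square
#'   with simulated p), `estimate`.
#' @export
assoc_compare <- function(a, b = NULL,
                          method = c("two_proportion_chi2", "unpaired_t",
                                     "one_sample_t"),
                          mu = 1) {
  method <- match.arg(method)
  if (method == "two_proportion_chi2") {
    stopifnot(length(a) == 2L, length(b) == 2L)
    tab <- rbind(c(a[1], a[2] - a[1]), c(b[1], b[2] - b[1]))
    if (any(tab < 0)) stop("n_associated exceeds n_nuclei")
    ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    est <- c(a[1] / a[2], b[1] / b[2])
  } else if (method == "unpaired_t") {
    if (length(a) < 2L || length(b) < 2L)
      stop("need >= 2 replicates per group for a t-test")
    ht <- stats::t.test(a, b, var.equal = TRUE)
    est <- unname(ht$estimate)
  } else {
    if (length(a) < 2L) stop("need >= 2 replicate ratios")
    if (stats::sd(a) == 0 && a[1] == mu) {
      # degenerate but well-defined null case: no deviation, no evidence
      return(list(method = method, statistic = 0, p_value = 1,
                  df = length(a) - 1, estimate = a[1]))
    }
    ht <- stats::t.test(a, mu = mu)
    est <- unname(ht$estimate)
  }
  list(method = method, statistic = unname(ht$statistic),
       p_value = ht$p.value,
       df = if (!is.null(ht$parameter)) unname(ht$parameter) else NA_real_,
       estimate = est)
}

#' Summarise a FISH scoring table
#'
#' Input format: one row per (label, replicate) with `n_nuclei` and
#' `n_associated`. Returns per-label pooled frequencies with Wilson intervals
#' and, when replicates are present, the replicate-level mean and s.e.m.
#'
#' @param scores data.frame with columns label, replicate, n_nuclei,
#'   n_associated (e.g. read from a TSV).
#' @return data.frame: label, n_replicates, n_nuclei, n_associated,
#'   frequency, lower, upper, rep_mean, rep_sem.
#' @export
summarise_fish_scores <- function(scores) {
  need <- c("label", "n_nuclei", "n_associated")
  if (!all(need %in% names(scores)))
    stop("scores needs columns label, n_nuclei, n_associated")
  out <- do.call(rbind, lapply(split(scores, scores$label), function(d) {
    f <- assoc_frequency(sum(d$n_associated), sum(d$n_nuclei))
    reps <- d$n_associated / d$n_nuclei
    data.frame(label = d$label[1], n_replicates = nrow(d),
               n_nuclei = sum(d$n_nuclei), n_associated = sum(d$n_associated),
               frequency = f$frequency, lower = f$lower, upper = f$upper,
               rep_mean = mean(reps),
               rep_sem = if (nrow(d) > 1)
                 stats::sd(reps) / sqrt(nrow(d)) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
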
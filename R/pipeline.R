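#' Pipeline configuration
#'
#' Bundles the thresholds used across the stages, with the defaults the
#' analysis was designed around: MAPQ floor 30, 100-bp windows, expressed
#' filter 1 RPKM, Xi-informative filter 5 SRPM, fold cutoffs 1.25/1.5/2.0,
#' dense-array metagene dialect. The Xi haplotype must be declared explicitly
#' (`xi_allele`): which strain carries the inactive X differs between
#' systems, so no default is safe.
#'
#' @param xi_allele "REF" or "ALT": haplotype on the inactive X.
#' @param mapq_min,window_size,rpkm_min,srpm_min,fold_cutoffs,dialect
#'   stage thresholds (see module functions).
#' @param sim a [sim_config()] used when the pipeline simulates its inputs.
#' @param seed master seed.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(xi_allele, mapq_min = 30L, window_size = 100L,
                            rpkm_min = 1, srpm_min = 5,
                            fold_cutoffs = c(1.25, 1.5, 2),
                            dialect = "nimblegen",
                            sim = sim_config(), seed = 1L) {
  cfg <- list(xi_allele = if (missing(xi_allele)) NULL else xi_allele,
              mapq_min = mapq_min, window_size = window_size,
              rpkm_min = rpkm_min, srpm_min = srpm_min,
              fold_cutoffs = fold_cutoffs, dialect = dialect, sim = sim,
              seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Validate a pipeline configuration
#'
#' Report-based: returns a character vector with one entry per invariant
#' violation; an empty vector means the configuration is runnable.
#'
#' @param config a [pipeline_config()] (or a bare list).
#' @return character vector of problems.
#' @export
validate_config <- function(config) {
  problems <- character()
  flag <- function(msg) problems <<- c(problems, msg)
  if (is.null(config$xi_allele))
    flag("xi_allele (strain orientation of the inactive X) not declared")
  else if (!config$xi_allele %in% c("REF", "ALT"))
    flag("xi_allele must be 'REF' or 'ALT'")
  for (f in c("mapq_min", "window_size", "rpkm_min", "srpm_min")) {
    v <- config[[f]]
    if (is.null(v) || !is.numeric(v) || length(v) != 1L || v < 0)
      flag(paste0(f, " must be a single non-negative number"))
  }
  if (!is.null(config$window_size) && isTRUE(config$window_size < 1))
    flag("window_size must be >= 1")
  if (is.null(config$fold_cutoffs) || any(config$fold_cutoffs <= 1))
    flag("fold_cutoffs must all exceed 1")
  if (!is.null(config$dialect) &&
      !config$dialect %in% c("nimblegen", "agilent"))
    flag("dialect must be 'nimblegen' or 'agilent'")
  for (p in config$paths)
    if (!file.exists(p)) flag(paste0("input file missing: ", p))
  problems
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML path.
#' @return `read_pipeline_config`: a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- do.call(sim_config, if (is.null(y$sim)) list() else y$sim)
  cfg <- pipeline_config(mapq_min = y$mapq_min %||% 30L,
                         window_size = y$window_size %||% 100L,
                         rpkm_min = y$rpkm_min %||% 1,
                         srpm_min = y$srpm_min %||% 5,
                         fold_cutoffs = y$fold_cutoffs %||% c(1.25, 1.5, 2),
                         dialect = y$dialect %||% "nimblegen",
                         sim = sim, seed = y$seed %||% 1L)
  cfg$xi_allele <- y$xi_allele
  cfg$paths <- y$paths
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname read_pipeline_config
#' @param config a [pipeline_config()].
#' @export
write_pipeline_config <- function(config, path) {
  y <- unclass(config)
  y$sim <- unclass(y$sim)
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Run the simulated end-to-end demo pipeline
#'
#' Exercises every stage on synthetic data: simulates a hybrid genome pair
#' and skewed reads, rebuilds the pseudo-genome, filters and classifies the
#' reads against the SNP table, aggregates 100-bp allelic window tracks, and
#' summarises the realized allelic skew. Results and a provenance manifest
#' (package version, config hash, per-stage record counts) are written under
#' `out_dir`; the run is deterministic given the config.
#'
#' @param config a [pipeline_config()] with `xi_allele` set.
#' @param out_dir output directory (created).
#' @return list with `manifest`, `track`, `classified`, `skew` (invisibly
#'   also written under `out_dir`).
#' @export
run_pipeline <- function(config, out_dir = tempfile("xallele_run_")) {
  problems <- validate_config(config)
  if (length(problems))
    stop("invalid configuration:\n  ", paste(problems, collapse = "\n  "))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr)
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  gp <- stage("simulate_genome", simulate_genome_pair(config$sim))
  pseudo <- stage("pseudogenome",
                  build_pseudogenome(gp$reference, gp$snps))
  sim <- stage("simulate_reads",
               simulate_reads(list(reference = gp$reference, pseudo = pseudo),
                              gp$snps, config$sim,
                              region_skew = c(chrX = config$sim$allelic_skew)))
  policy <- filter_policy(mapq_min = config$mapq_min)
  retained <- stage("filter", filter_alignments(sim$alignments, policy))
  classified <- stage("classify", classify_reads(retained, gp$snps))
  track <- stage("windows",
                 count_windows(classified, config$window_size, gp$reference))
  paths <- stage("export", export_tracks(track, c("total", "ref", "alt"),
                                         dir = out_dir, prefix = "demo"))
  x <- classified[classified$chrom == "chrX", , drop = FALSE]
  informative <- x$category %in% c("REF", "ALT")
  skew <- sum(x$category == "ALT") / max(1L, sum(informative))
  write_snp_table(gp$snps, file.path(out_dir, "snps.tsv"))
  write_classified_tsv(classified, file.path(out_dir, "classified.tsv"))
  cfg_yaml <- file.path(out_dir, "config.yaml")
  write_pipeline_config(config, cfg_yaml)
  manifest <- list(
    package = "xallele",
    version = as.character(utils::packageVersion("xallele")),
    config_md5 = unname(tools::md5sum(cfg_yaml)),
    seed = config$seed,
    counts = list(snps = nrow(gp$snps),
                  reads_simulated = nrow(sim$alignments),
                  reads_retained = nrow(retained),
                  reads_classified = nrow(classified),
                  ref = sum(classified$category == "REF"),
                  alt = sum(classified$category == "ALT"),
                  ambiguous = sum(classified$category == "AMBIGUOUS")),
    realized_x_skew = skew,
    outputs = c(paths, snps = file.path(out_dir, "snps.tsv")))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  list(manifest = manifest, track = track, classified = classified,
       skew = skew, out_dir = out_dir)
}
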
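#' Read a pipeline run configuration
#'
#' YAML configuration with sections `out_dir`, `paths` (track, chrom_sizes,
#' features as a name->path map, genes), `normalization`, `locks`, `eis`,
#' `enrich`, and `simulate`.  Missing parameter keys fall back to the
#' package defaults of the corresponding `*_params()` constructors.
#'
#' @param path path to a YAML file.
#' @param out_dir override for the configured output directory.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path, out_dir = NULL) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  cfg <- yaml::read_yaml(path)
  if (!is.null(out_dir)) cfg$out_dir <- out_dir
  if (is.null(cfg$out_dir)) cfg$out_dir <- "."
  for (p in unlist(cfg$paths)) {
    if (!file.exists(p)) stopf("configured input does not exist: %s", p)
  }
  structure(cfg, class = "run_config")
}

out_path <- function(config, ...) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  file.path(config$out_dir, ...)
}

# provenance sidecar: parameters, computed thresholds, seed, input checksums
write_provenance <- function(config, stage, info, inputs = character()) {
  info$stage <- stage
  info$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  if (length(inputs)) {
    info$input_md5 <- as.list(tools::md5sum(inputs))
  }
  p <- out_path(config, paste0(stage, ".provenance.json"))
  jsonlite::write_json(info, p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(p)
}

cfg_params <- function(config, section, constructor) {
  args <- config[[section]]
  if (is.null(args)) args <- list()
  do.call(constructor, args)
}

#' Pipeline stages
#'
#' Each stage reads its inputs from the configuration, writes its outputs
#' (BED/bedGraph/TSV) into `out_dir` together with a provenance JSON sidecar
#' recording parameters, computed thresholds, the seed, and input checksums.
#' `run_all()` chains simulate (when a `simulate` section is present),
#' normalize, LOCK calling, island detection and enrichment, and writes a
#' combined summary.
#'
#' @param config a `run_config` from [read_run_config()], or a path to one.
#' @return Each stage invisibly returns the paths it wrote; `run_all()`
#'   returns them all plus the summary path.
#' @name pipeline
NULL

as_config <- function(config) {
  if (is.character(config)) read_run_config(config) else config
}

#' @rdname pipeline
#' @export
run_simulate <- function(config) {
  config <- as_config(config)
  sim <- config$simulate
  if (is.null(sim)) stopf("config has no 'simulate' section")
  spec <- do.call(sim_spec, sim)
  res <- simulate_track(spec, seed = spec$seed)
  feats <- simulate_features(res$truth, seed = if (is.null(spec$seed)) NULL
                             else spec$seed + 2L)
  paths <- c(track = out_path(config, "simulated_track.bedgraph"),
             sizes = out_path(config, "simulated.chrom.sizes"),
             locks = out_path(config, "truth_locks.bed"),
             eis = out_path(config, "truth_eis.bed"),
             features = out_path(config, "simulated_features.bed"))
  write_probe_track(res$track, paths[["track"]])
  lay <- res$truth$layout
  utils::write.table(
    data.frame(GenomeInfoDb::seqnames(lay), GenomeInfoDb::seqlengths(lay)),
    paths[["sizes"]], sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  write_bed(res$truth$locks, paths[["locks"]])
  write_bed(GenomicRanges::granges(res$truth$eis), paths[["eis"]])
  write_bed(feats, paths[["features"]])
  write_provenance(config, "simulate",
                   list(spec = unclass(spec), seed = spec$seed))
  invisible(paths)
}

#' @rdname pipeline
#' @export
run_normalize <- function(config) {
  config <- as_config(config)
  layout <- read_chrom_sizes(config$paths$chrom_sizes)
  track_paths <- unlist(config$paths$track)
  tracks <- lapply(track_paths, read_probe_track, layout = layout)
  norm <- config$normalization
  if (is.null(norm)) norm <- list()
  lf <- if (is.null(norm$lower_fraction)) 0.75 else norm$lower_fraction
  ref <- if (is.null(norm$reference)) "mean-quantile-curve" else norm$reference
  normed <- partial_quantile_normalize(tracks, lower_fraction = lf,
                                       reference = ref)
  paths <- vapply(seq_along(normed), function(i) {
    p <- out_path(config, sprintf("normalized_%d.bedgraph", i))
    write_probe_track(normed[[i]], p)
    p
  }, character(1))
  write_provenance(config, "normalize",
                   list(lower_fraction = lf, reference = ref,
                        boundaries = lapply(normed, function(tr)
                          S4Vectors::metadata(tr)$normalization)),
                   inputs = track_paths)
  invisible(paths)
}

#' @rdname pipeline
#' @export
run_call_locks <- function(config, track_path = NULL) {
  config <- as_config(config)
  layout <- read_chrom_sizes(config$paths$chrom_sizes)
  if (is.null(track_path)) {
    track_path <- out_path(config, "normalized_1.bedgraph")
    if (!file.exists(track_path)) track_path <- unlist(config$paths$track)[1]
  }
  track <- read_probe_track(track_path, layout)
  params <- cfg_params(config, "locks", lock_params)
  locks <- call_locks(track, params)
  bed <- GenomicRanges::granges(locks)
  bed$name <- sprintf("LOCK_%d", seq_along(locks))
  bed$score <- pmin(1000, pmax(0, round(locks$mean_smoothed * 1000)))
  lock_bed <- out_path(config, "locks.bed")
  write_bed(bed, lock_bed)
  summ <- lock_summary(locks, layout)
  summ_path <- out_path(config, "lock_summary.tsv")
  utils::write.table(cbind(cutoff_quantile = params$quantile,
                           threshold = S4Vectors::metadata(locks)$threshold,
                           summ),
                     summ_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write_provenance(config, "call_locks",
                   list(params = unclass(params),
                        threshold = S4Vectors::metadata(locks)$threshold,
                        n_domains = length(locks)),
                   inputs = track_path)
  invisible(c(locks = lock_bed, summary = summ_path))
}

#' @rdname pipeline
#' @export
run_call_eis <- function(config, track_path = NULL, locks_path = NULL) {
  config <- as_config(config)
  layout <- read_chrom_sizes(config$paths$chrom_sizes)
  if (is.null(track_path)) {
    track_path <- out_path(config, "normalized_1.bedgraph")
    if (!file.exists(track_path)) track_path <- unlist(config$paths$track)[1]
  }
  if (is.null(locks_path)) locks_path <- out_path(config, "locks.bed")
  track <- read_probe_track(track_path, layout)
  locks <- read_bed(locks_path, layout)
  params <- cfg_params(config, "eis", ei_params)
  if (length(locks) == 0L) {
    warning("run_call_eis: empty LOCK set; writing empty island BED",
            call. = FALSE)
  }
  eis <- detect_eis(track, locks, params)
  bed <- GenomicRanges::granges(eis)
  if (length(eis)) {
    bed$name <- sprintf("LOCK_%d", eis$parent_lock)
    bed$score <- pmin(1000, pmax(0, round(-eis$min_smoothed * 100)))
  }
  ei_bed <- out_path(config, "eis.bed")
  write_bed(bed, ei_bed)
  summ <- ei_summary(eis)
  summ_path <- out_path(config, "ei_summary.tsv")
  utils::write.table(
    data.frame(n_eis = summ$n, mean_size_bp = summ$mean_size_bp),
    summ_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write_provenance(config, "call_eis",
                   list(params = unclass(params),
                        threshold = S4Vectors::metadata(eis)$threshold,
                        n_eis = length(eis)),
                   inputs = c(track_path, locks_path))
  invisible(c(eis = ei_bed, summary = summ_path))
}

#' @rdname pipeline
#' @export
run_enrich <- function(config, track_path = NULL) {
  config <- as_config(config)
  layout <- read_chrom_sizes(config$paths$chrom_sizes)
  if (is.null(track_path)) {
    track_path <- out_path(config, "normalized_1.bedgraph")
    if (!file.exists(track_path)) track_path <- unlist(config$paths$track)[1]
  }
  track <- read_probe_track(track_path, layout)
  eis <- read_bed(out_path(config, "eis.bed"), layout)
  if (length(eis) == 0L) stopf("run_enrich: empty island set")
  en <- config$enrich
  if (is.null(en)) en <- list()
  universe_kind <- if (is.null(en$universe)) "whole-genome" else en$universe
  en$universe <- NULL
  params <- do.call(enrich_params, en)
  universe <- switch(universe_kind,
    "whole-genome" = probe_universe(track),
    "within-LOCKs" = read_bed(out_path(config, "locks.bed"), layout),
    stopf("unknown enrich universe: %s", universe_kind))
  feat_paths <- config$paths$features
  if (is.null(feat_paths)) stopf("config has no paths$features")
  rows <- lapply(names(feat_paths), function(nm) {
    feats <- read_bed(feat_paths[[nm]], layout, name = nm)
    permutation_enrichment(eis, feats, universe, params, feature_name = nm)
  })
  res <- bonferroni_adjust(rows)
  res_path <- out_path(config, "enrichment.tsv")
  utils::write.table(res, res_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_provenance(config, "enrich",
                   list(params = unclass(params), universe = universe_kind,
                        features = as.list(feat_paths)),
                   inputs = unlist(feat_paths))
  invisible(res_path)
}

#' @rdname pipeline
#' @export
run_all <- function(config) {
  config <- as_config(config)
  paths <- character()
  if (!is.null(config$simulate)) {
    sim_paths <- run_simulate(config)
    config$paths$track <- sim_paths[["track"]]
    config$paths$chrom_sizes <- sim_paths[["sizes"]]
    if (is.null(config$paths$features)) {
      config$paths$features <- list(simulated = sim_paths[["features"]])
    }
    paths <- c(paths, sim_paths)
  }
  paths <- c(paths, run_normalize(config))
  paths <- c(paths, run_call_locks(config))
  paths <- c(paths, run_call_eis(config))
  paths <- c(paths, enrichment = run_enrich(config))
  invisible(paths)
}
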
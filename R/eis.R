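#' Parameters for euchromatin-island detection
#'
#' Defaults follow the published algorithm: in-LOCK probes smoothed with a
#' 5,000 bp window; regions with smoothed value below the 1st percentile of
#' all smoothed values are islands; islands must be at least 1,000 bp long
#' and contain at least 10 probes; islands less than 1,000 bp apart are
#' merged; islands must lie at least 20,000 bp from the LOCK boundaries
#' (log ratios decay at boundaries, and the margin prevents mistaking that
#' decay for islands).
#'
#' @param window_bp smoothing window in bp (default 5,000; short, to capture
#'   signal variation in small regions).
#' @param low_percentile threshold percentile in (0, 0.5) (default 0.01).
#' @param min_length_bp minimum island span in bp (default 1,000).
#' @param min_probes minimum probes per island (default 10).
#' @param merge_gap_bp islands closer than this are merged (strict `<`;
#'   default 1,000).
#' @param boundary_margin_bp minimum edge-to-edge distance from the parent
#'   LOCK boundary (default 20,000).
#' @param percentile_universe values pooled for the threshold quantile:
#'   `"within-LOCK"` (default; the smoothed values of probes inside LOCKs)
#'   or `"all-probes"` (the whole track smoothed genome-wide with the same
#'   window).
#' @return An `ei_params` list.
#' @export
ei_params <- function(window_bp = 5000, low_percentile = 0.01,
                      min_length_bp = 1000, min_probes = 10,
                      merge_gap_bp = 1000, boundary_margin_bp = 20000,
                      percentile_universe = c("within-LOCK", "all-probes")) {
  percentile_universe <- match.arg(percentile_universe)
  stopifnot(is_count(window_bp), is_count(min_length_bp), is_count(min_probes),
            is_count(merge_gap_bp), is_count(boundary_margin_bp),
            is.numeric(low_percentile), length(low_percentile) == 1L,
            low_percentile > 0, low_percentile < 0.5)
  structure(list(window_bp = window_bp, low_percentile = low_percentile,
                 min_length_bp = min_length_bp, min_probes = min_probes,
                 merge_gap_bp = merge_gap_bp,
                 boundary_margin_bp = boundary_margin_bp,
                 percentile_universe = percentile_universe),
            class = "ei_params")
}

#' Detect euchromatin islands inside LOCK bodies
#'
#' Steps, in order: (1) restrict to probes inside LOCKs; (2) smooth those
#' probes with `window_bp`, per LOCK, so the window never crosses a LOCK
#' boundary; (3) set the threshold `t` to the `low_percentile` quantile of
#' the smoothed values in the chosen universe; (4) take maximal runs of
#' consecutive probes with smoothed value strictly below `t`; (5) merge runs
#' whose gap is `< merge_gap_bp`; (6) drop merged runs shorter than
#' `min_length_bp` or with fewer than `min_probes` probes; (7) drop runs
#' whose nearest edge is `< boundary_margin_bp` from the parent LOCK's edge.
#' Island coordinates span the first to the last probe of the run.
#'
#' @param track normalized probe track `GRanges` (same grid the LOCKs were
#'   called on).
#' @param locks `GRanges` of called LOCKs.
#' @param params an [ei_params()] list.
#' @return A `GRanges` of islands with metadata columns `parent_lock`
#'   (index into `locks`), `n_probes`, `min_smoothed`; `metadata(x)` records
#'   the params and the computed threshold.  Empty `locks` give an empty
#'   island set.
#' @export
detect_eis <- function(track, locks, params = ei_params()) {
  stopifnot(inherits(params, "ei_params"))
  track <- validate_probe_track(track)
  empty <- GenomicRanges::GRanges(seqinfo = GenomeInfoDb::seqinfo(track))
  empty$parent_lock <- integer(0)
  empty$n_probes <- integer(0)
  empty$min_smoothed <- numeric(0)
  S4Vectors::metadata(empty)$params <- params
  if (length(locks) == 0L) return(empty)

  hits <- GenomicRanges::findOverlaps(track, locks, ignore.strand = TRUE)
  if (length(hits) == 0L) {
    stopf("detect_eis: no probes fall inside the supplied LOCKs (grid mismatch?)")
  }
  pidx <- S4Vectors::queryHits(hits)
  lock_of <- S4Vectors::subjectHits(hits)
  # smooth per LOCK: truncated windows at LOCK edges, never across them
  sm <- numeric(length(pidx))
  for (l in unique(lock_of)) {
    sel <- lock_of == l
    i <- pidx[sel]
    sm[sel] <- smooth_values(GenomicRanges::start(track)[i],
                             GenomicRanges::end(track)[i],
                             track$score[i], params$window_bp)
  }
  universe_vals <- if (params$percentile_universe == "within-LOCK") {
    sm
  } else {
    smooth_track(track, params$window_bp)$score
  }
  t_val <- q7(universe_vals, params$low_percentile)
  flag <- sm < t_val

  sub <- track[pidx]
  runs <- flag_runs(lock_of, flag)
  eis <- runs_to_domains(runs, sub, sm,
                         merge_gap_bp = params$merge_gap_bp,
                         gap_strict = TRUE,
                         min_length_bp = params$min_length_bp,
                         min_probes = params$min_probes)
  if (length(eis) == 0L) {
    S4Vectors::metadata(empty)$threshold <- t_val
    return(empty)
  }
  # recover parent lock and apply the boundary-margin filter (final edges)
  parent <- GenomicRanges::findOverlaps(eis, locks, ignore.strand = TRUE,
                                        select = "first")
  left <- GenomicRanges::start(eis) - GenomicRanges::start(locks)[parent]
  right <- GenomicRanges::end(locks)[parent] - GenomicRanges::end(eis)
  keep <- left >= params$boundary_margin_bp & right >= params$boundary_margin_bp
  eis <- eis[keep]
  eis$parent_lock <- parent[keep]
  eis$mean_smoothed <- NULL
  S4Vectors::metadata(eis)$params <- params
  S4Vectors::metadata(eis)$threshold <- t_val
  eis
}

#' Summarize an island set
#'
#' @param eis `GRanges` of islands from [detect_eis()].
#' @return A list with `n`, `mean_size_bp`, and `per_lock` (a table of island
#'   counts per parent LOCK).
#' @export
ei_summary <- function(eis) {
  w <- as.numeric(GenomicRanges::width(eis))
  list(n = length(eis),
       mean_size_bp = if (length(w)) mean(w) else NA_real_,
       per_lock = if (!is.null(eis$parent_lock)) table(eis$parent_lock)
                  else table(integer(0)))
}

#' Concordance between two island sets
#'
#' Fraction of the islands in `a` that overlap (share at least 1 bp with)
#' any island in `b`; the replicate-agreement statistic.
#'
#' @param a,b island `GRanges` on the same layout; `a` must be nonempty.
#' @return Fraction in \[0, 1\].
#' @export
ei_concordance <- function(a, b) {
  interval_overlap_fraction(a, b)
}
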
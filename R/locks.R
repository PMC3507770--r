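#' Parameters for LOCK calling
#'
#' @param window_bp smoothing window (bp) for the domain-scale smoothed
#'   curve; default 10,000.
#' @param quantile genome-wide cutoff quantile in (0, 1); default 0.90 (the
#'   90th-quantile cutoff used to define large domains).
#' @param min_length_bp minimum domain length after merging; default 100,000,
#'   the lower edge of the large-domain (10^2 - 10^3 kb) scale, which also
#'   rejects chance chains of isolated above-cutoff probes.
#' @param merge_gap_bp runs separated by at most this many bp are merged;
#'   default 15,000, chosen above the scale of intra-domain islands so a deep
#'   euchromatin island cannot split its parent domain at calling time.
#' @param edge_min_probes a domain edge must be anchored by a run of at
#'   least this many consecutive above-cutoff probes (default 2); isolated
#'   single-probe runs still merge for continuity but cannot extend a
#'   domain boundary outward into background.
#' @param min_enrichment a called domain must contain above-cutoff probes
#'   at a rate at least `min_enrichment` times the genome-wide rate
#'   `1 - quantile` (default 1.5).  At the cutoff quantile itself 10% of
#'   probes lie above threshold anywhere, so without a local-enrichment
#'   requirement chance probes chain through the merge gap into spurious
#'   chromosome-scale domains on structureless tracks.
#' @param threshold_source `"raw"` (default): both the cutoff quantile and
#'   the run statistic are the raw probe values, so a domain is a merged run
#'   of probes exceeding the genome-wide raw cutoff.  `"smoothed"`: both use
#'   the smoothed curve.  The raw mode lets spatially coherent moderate
#'   enrichment cover well over `1 - quantile` of the genome, which is how
#'   broad-domain coverage near 40% arises from a 90th-percentile cutoff.
#' @return A `lock_params` list.
#' @export
lock_params <- function(window_bp = 10000, quantile = 0.90,
                        min_length_bp = 100000, merge_gap_bp = 15000,
                        threshold_source = c("raw", "smoothed"),
                        edge_min_probes = 2L, min_enrichment = 1.5) {
  threshold_source <- match.arg(threshold_source)
  stopifnot(is_count(window_bp), is_count(min_length_bp), is_count(merge_gap_bp),
            is.numeric(quantile), length(quantile) == 1L,
            quantile > 0, quantile < 1, is_count(edge_min_probes),
            is.numeric(min_enrichment), min_enrichment >= 0)
  structure(list(window_bp = window_bp, quantile = quantile,
                 min_length_bp = min_length_bp, merge_gap_bp = merge_gap_bp,
                 threshold_source = threshold_source,
                 edge_min_probes = as.integer(edge_min_probes),
                 min_enrichment = min_enrichment),
            class = "lock_params")
}

#' Call LOCKs (large H3K9me2 domains) from a normalized probe track
#'
#' The cutoff `t` is the genome-wide `quantile` of the probe values (raw or
#' smoothed per `threshold_source`); candidate runs are maximal stretches of
#' consecutive probes whose statistic is `>= t` (ties included); runs on the
#' same chromosome separated by `<= merge_gap_bp` are merged; merged runs
#' shorter than `min_length_bp` are discarded.  Domain coordinates span from
#' the first probe start to the last probe end of the run.
#'
#' @param track normalized probe track `GRanges`.
#' @param params a [lock_params()] list.
#' @param smoothed optional pre-smoothed track on the same grid; computed
#'   with `params$window_bp` when omitted.
#' @return A `GRanges` of pairwise-disjoint domains with metadata columns
#'   `n_probes` and `mean_smoothed`; `metadata(x)` records the params and the
#'   computed threshold.
#' @export
call_locks <- function(track, params = lock_params(), smoothed = NULL) {
  stopifnot(inherits(params, "lock_params"))
  track <- validate_probe_track(track)
  if (length(track) == 0L) stopf("call_locks: empty track")
  if (is.null(smoothed)) {
    smoothed <- smooth_track(track, params$window_bp)
  } else {
    smoothed <- validate_probe_track(smoothed, "smoothed")
    if (length(smoothed) != length(track) ||
        !all(GenomicRanges::start(smoothed) == GenomicRanges::start(track))) {
      stopf("call_locks: smoothed track is not on the raw track's probe grid")
    }
  }
  stat <- if (params$threshold_source == "raw") track$score else smoothed$score
  t_val <- q7(stat, params$quantile)
  flag <- stat >= t_val

  chrom <- as.integer(GenomicRanges::seqnames(track))
  runs <- flag_runs(chrom, flag)
  dom <- runs_to_domains(runs, track, smoothed$score,
                         merge_gap_bp = params$merge_gap_bp,
                         gap_strict = FALSE,
                         min_length_bp = params$min_length_bp,
                         edge_min_probes = params$edge_min_probes,
                         flag = flag,
                         min_flag_frac = params$min_enrichment *
                           (1 - params$quantile))
  S4Vectors::metadata(dom)$params <- params
  S4Vectors::metadata(dom)$threshold <- t_val
  dom
}

# merge runs, trim noise-anchored edges, apply the min-length filter, and
# materialize domains as GRanges
runs_to_domains <- function(runs, track, smoothed_values, merge_gap_bp,
                            gap_strict, min_length_bp, min_probes = 0L,
                            edge_min_probes = 1L, flag = NULL,
                            min_flag_frac = 0) {
  empty <- GenomicRanges::GRanges(seqinfo = GenomeInfoDb::seqinfo(track))
  empty$n_probes <- integer(0)
  empty$mean_smoothed <- numeric(0)
  empty$min_smoothed <- numeric(0)
  if (nrow(runs) == 0L) return(empty)
  rs <- GenomicRanges::start(track)[runs$first]
  re <- GenomicRanges::end(track)[runs$last]
  runs <- merge_runs(runs, rs, re, merge_gap_bp, strict = gap_strict)
  runs <- trim_edge_runs(runs, edge_min_probes)
  if (nrow(runs) == 0L) return(empty)
  first <- tapply(runs$first, runs$merge_id, min)
  last <- tapply(runs$last, runs$merge_id, max)
  first <- as.integer(first); last <- as.integer(last)
  gs <- GenomicRanges::start(track)[first]
  ge <- GenomicRanges::end(track)[last]
  len <- ge - gs + 1
  np <- last - first + 1L
  keep <- len >= min_length_bp & np >= min_probes
  if (!is.null(flag) && min_flag_frac > 0) {
    cf <- c(0L, cumsum(flag))
    frac <- (cf[last + 1L] - cf[first]) / np
    keep <- keep & frac >= min_flag_frac
  }
  if (!any(keep)) return(empty)
  first <- first[keep]; last <- last[keep]
  stats_of <- function(f, l, fun) {
    vapply(seq_along(f),
           function(i) fun(smoothed_values[f[i]:l[i]]), numeric(1))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = GenomicRanges::seqnames(track)[first],
    ranges = IRanges::IRanges(start = gs[keep], end = ge[keep]),
    seqinfo = GenomeInfoDb::seqinfo(track))
  gr$n_probes <- last - first + 1L
  gr$mean_smoothed <- stats_of(first, last, mean)
  gr$min_smoothed <- stats_of(first, last, min)
  GenomicRanges::sort(gr, ignore.strand = TRUE)
}

#' Summarize a called domain set
#'
#' @param domains `GRanges` of called LOCKs.
#' @param layout [GenomeInfoDb::Seqinfo] layout the calls were made on.
#' @return A one-row [tibble::tibble] with `n`, `coverage` (fraction of the
#'   genome inside domains), `total_bp`, `mean_size_bp`, `median_size_bp`.
#' @export
lock_summary <- function(domains, layout) {
  w <- as.numeric(GenomicRanges::width(domains))
  tibble::tibble(
    n = length(domains),
    coverage = sum(w) / layout_size(layout),
    total_bp = sum(w),
    mean_size_bp = if (length(w)) mean(w) else NA_real_,
    median_size_bp = if (length(w)) stats::median(w) else NA_real_)
}
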
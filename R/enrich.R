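#' Parameters for permutation enrichment tests
#'
#' @param n_permutations number of random interval sets forming the null
#'   distribution (>= 100; default 1,000).
#' @param statistic `"interval-overlap"` (fraction of query intervals hitting
#'   any feature; default) or `"base-overlap"` (fraction of query bp covered
#'   by features).
#' @param seed RNG seed; given a seed the whole test is bit-reproducible.
#' @param allow_overlap_in_null allow sampled null intervals to overlap each
#'   other (default `FALSE`: null sets are pairwise disjoint, like the
#'   island sets they emulate).
#' @param max_attempts rejection-sampling cap per interval when null
#'   intervals must be disjoint.
#' @return An `enrich_params` list.
#' @export
enrich_params <- function(n_permutations = 1000,
                          statistic = c("interval-overlap", "base-overlap"),
                          seed = NULL, allow_overlap_in_null = FALSE,
                          max_attempts = 1000) {
  statistic <- match.arg(statistic)
  if (!is_count(n_permutations) || n_permutations < 100) {
    stopf("n_permutations must be at least 100")
  }
  structure(list(n_permutations = as.integer(n_permutations),
                 statistic = statistic, seed = seed,
                 allow_overlap_in_null = isTRUE(allow_overlap_in_null),
                 max_attempts = as.integer(max_attempts)),
            class = "enrich_params")
}

# --- fast numeric kernels -------------------------------------------------
# universe segments as parallel vectors; features as a per-chromosome index
# of merged intervals with prefix-summed widths, so overlap statistics for
# sampled intervals are findInterval arithmetic, not range-object operations.

universe_segments <- function(universe) {
  u <- GenomicRanges::reduce(GenomicRanges::granges(universe),
                             ignore.strand = TRUE)
  if (length(u) == 0L) stopf("empty universe")
  list(chrom = as.character(GenomicRanges::seqnames(u)),
       start = GenomicRanges::start(u),
       width = GenomicRanges::width(u))
}

feature_index <- function(features) {
  f <- GenomicRanges::reduce(GenomicRanges::granges(features),
                             ignore.strand = TRUE)
  ch <- as.character(GenomicRanges::seqnames(f))
  lapply(split(seq_along(f), ch), function(i) {
    s <- GenomicRanges::start(f)[i]
    e <- GenomicRanges::end(f)[i]
    list(start = s, end = e, cum = cumsum(as.numeric(e - s + 1)))
  })
}

# feature bp at positions <= x on one chromosome index
covered_upto <- function(x, idx) {
  j <- findInterval(x, idx$start)
  out <- numeric(length(x))
  nz <- j > 0L
  out[nz] <- idx$cum[j[nz]] - pmax(0, idx$end[j[nz]] - x[nz])
  out
}

# per-interval bp of overlap with the (merged) feature set
intersect_bp <- function(chrom, start, end, fidx) {
  out <- numeric(length(start))
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    idx <- fidx[[ch]]
    if (is.null(idx)) next
    out[sel] <- covered_upto(end[sel], idx) - covered_upto(start[sel] - 1, idx)
  }
  out
}

# place length-matched intervals uniformly in the universe segments;
# returns list(chrom, start, end) with widths in non-increasing order
place_matched <- function(widths, segs, allow_overlap = FALSE,
                          max_attempts = 1000L) {
  widths <- sort(as.numeric(widths), decreasing = TRUE)
  k <- length(widths)
  chrom <- character(k); s <- numeric(k); e <- numeric(k)
  nseg <- length(segs$width)
  for (i in seq_len(k)) {
    L <- widths[i]
    valid <- pmax(0, segs$width - L + 1)
    if (all(valid == 0)) {
      stopf("an interval of %d bp is longer than every universe segment", L)
    }
    placed <- FALSE
    for (att in seq_len(max_attempts)) {
      g <- if (nseg == 1L) 1L else
        sample.int(nseg, 1L, prob = valid)
      st <- segs$start[g] + sample.int(valid[g], 1L) - 1
      en <- st + L - 1
      if (allow_overlap || i == 1L) { placed <- TRUE; break }
      prev <- seq_len(i - 1L)
      clash <- chrom[prev] == segs$chrom[g] & s[prev] <= en & e[prev] >= st
      if (!any(clash)) { placed <- TRUE; break }
    }
    if (!placed) {
      stopf(paste("could not place disjoint null intervals after %d attempts;",
                  "consider allow_overlap_in_null = TRUE"), max_attempts)
    }
    chrom[i] <- segs$chrom[g]; s[i] <- st; e[i] <- en
  }
  list(chrom = chrom, start = s, end = e)
}

#' Sample a length-matched random interval set
#'
#' Draws exactly `length(query)` intervals whose multiset of lengths equals
#' the query's, each placed uniformly at random wholly inside a universe
#' segment (segments chosen with probability proportional to their number of
#' valid start positions for that length).  This is the null model of the
#' enrichment tests: the number and lengths of the random regions match the
#' island list.
#'
#' @param query `GRanges` whose interval lengths are matched.
#' @param universe `GRanges` of allowed placement segments (merged
#'   internally), e.g. the probe-covered genome or the LOCK set.
#' @param allow_overlap allow sampled intervals to overlap each other.
#' @param max_attempts rejection cap per interval when disjoint.
#' @return A sorted `GRanges` of sampled intervals.
#' @export
sample_matched <- function(query, universe, allow_overlap = FALSE,
                           max_attempts = 1000L) {
  if (length(query) == 0L) stopf("sample_matched: empty query")
  segs <- universe_segments(universe)
  pl <- place_matched(GenomicRanges::width(query), segs,
                      allow_overlap = allow_overlap,
                      max_attempts = max_attempts)
  GenomicRanges::sort(GenomicRanges::GRanges(
    seqnames = pl$chrom,
    ranges = IRanges::IRanges(start = pl$start, end = pl$end),
    seqinfo = GenomeInfoDb::seqinfo(universe)), ignore.strand = TRUE)
}

#' Length-matched permutation enrichment test
#'
#' Computes the observed overlap statistic of `query` against `features`,
#' builds a null distribution from `n_permutations` length-matched random
#' interval sets drawn in `universe`, and reports fold enrichment
#' (observed / null mean) and the upper-tail empirical p-value with the
#' add-one rule `p = (1 + #(null >= observed)) / (n + 1)`, so p is never 0
#' and the minimum reportable p at n = 1,000 is 1/1001 (the "< 10^-3"
#' convention).  Degenerate folds: 0/0 is reported as 1; positive/0 as
#' `Inf` with p = 1/(n + 1).
#'
#' @param query nonempty `GRanges` (e.g. an island set).
#' @param features `GRanges` feature set.
#' @param universe `GRanges` placement universe for the null (whole
#'   probe-covered genome, the LOCK set, or any explicit segment set).
#' @param params an [enrich_params()] list.
#' @param feature_name label for the output row; defaults to
#'   `metadata(features)$name`.
#' @param keep_null attach the null draws as `attr(x, "null")`.
#' @return A one-row [tibble::tibble]: `feature`, `statistic`, `observed`,
#'   `null_mean`, `null_sd`, `fold`, `p_raw`, `p_bonferroni` (`NA` until
#'   [bonferroni_adjust()]), `n_permutations`, `seed`.
#' @export
permutation_enrichment <- function(query, features, universe,
                                   params = enrich_params(),
                                   feature_name = NULL, keep_null = FALSE) {
  stopifnot(inherits(params, "enrich_params"))
  if (length(query) == 0L) stopf("permutation_enrichment: empty query")
  if (is.null(feature_name)) {
    feature_name <- S4Vectors::metadata(features)$name
    if (is.null(feature_name)) feature_name <- "features"
  }
  observed <- if (params$statistic == "interval-overlap") {
    if (length(features)) interval_overlap_fraction(query, features) else 0
  } else {
    if (length(features)) base_overlap_fraction(query, features) else 0
  }
  segs <- universe_segments(universe)
  fidx <- feature_index(features)
  widths <- as.numeric(GenomicRanges::width(query))
  nulls <- with_seed(params$seed, {
    vapply(seq_len(params$n_permutations), function(b) {
      pl <- place_matched(widths, segs,
                          allow_overlap = params$allow_overlap_in_null,
                          max_attempts = params$max_attempts)
      bp <- intersect_bp(pl$chrom, pl$start, pl$end, fidx)
      if (params$statistic == "interval-overlap") mean(bp > 0)
      else sum(bp) / sum(widths)
    }, numeric(1))
  })
  null_mean <- mean(nulls)
  fold <- if (null_mean == 0) {
    if (observed == 0) 1 else Inf
  } else {
    observed / null_mean
  }
  p_raw <- if (null_mean == 0 && observed > 0) {
    1 / (params$n_permutations + 1)
  } else {
    (1 + sum(nulls >= observed)) / (params$n_permutations + 1)
  }
  res <- tibble::tibble(
    feature = feature_name, statistic = params$statistic,
    observed = observed, null_mean = null_mean, null_sd = stats::sd(nulls),
    fold = fold, p_raw = p_raw, p_bonferroni = NA_real_,
    n_permutations = params$n_permutations,
    seed = if (is.null(params$seed)) NA_integer_ else params$seed)
  if (keep_null) attr(res, "null") <- nulls
  res
}

#' Bonferroni correction within a family of enrichment results
#'
#' @param results a tibble of rows from [permutation_enrichment()] (one
#'   family), or a list of such tibbles which is row-bound first.
#' @return The tibble with `p_bonferroni = min(1, p_raw * family size)`;
#'   row order preserved.
#' @export
bonferroni_adjust <- function(results) {
  if (is.list(results) && !is.data.frame(results)) {
    results <- do.call(rbind, results)
  }
  results$p_bonferroni <- pmin(1, results$p_raw * nrow(results))
  results
}

#' Base-level domain overlap permutation test
#'
#' The domain-vs-block statistic (e.g. fraction of LOCK bp coinciding with
#' partially methylated domains), tested against length-matched random
#' domain placements over the whole genome.
#'
#' @param locks nonempty `GRanges` of domains (the query).
#' @param blocks `GRanges` of comparison blocks.
#' @param layout [GenomeInfoDb::Seqinfo]; the null universe is the full
#'   chromosome spans.
#' @param params an [enrich_params()] list; the statistic is forced to
#'   `"base-overlap"`.
#' @return A one-row tibble as in [permutation_enrichment()].
#' @export
domain_base_overlap_test <- function(locks, blocks, layout,
                                     params = enrich_params()) {
  params$statistic <- "base-overlap"
  permutation_enrichment(locks, blocks, layout_ranges(layout), params,
                         feature_name = S4Vectors::metadata(blocks)$name)
}
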
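#' Interval-level overlap fraction
#'
#' Fraction of query intervals that share at least one bp with any feature
#' interval.  This is the "percent of EIs overlapping the feature" statistic
#' used throughout the enrichment analyses.
#'
#' @param query `GRanges` of query intervals (e.g. an EI set); must be
#'   nonempty.
#' @param features `GRanges` of feature intervals (may overlap each other).
#' @param min_overlap_bp minimum shared bp to count as overlap (default 1).
#' @return Fraction in \[0, 1\].
#' @export
interval_overlap_fraction <- function(query, features, min_overlap_bp = 1L) {
  if (length(query) == 0L) {
    stopf("interval_overlap_fraction: empty query set (fraction undefined)")
  }
  hit <- IRanges::overlapsAny(query, features, minoverlap = min_overlap_bp,
                              ignore.strand = TRUE)
  mean(hit)
}

#' Base-level overlap fraction
#'
#' Fraction of query bp covered by the union of the feature intervals; the
#' statistic behind domain-vs-domain comparisons such as LOCK/PMD coincidence.
#' Features are merged before computation so overlapping features are not
#' double counted.
#'
#' @inheritParams interval_overlap_fraction
#' @return Fraction in \[0, 1\].
#' @export
base_overlap_fraction <- function(query, features) {
  if (length(query) == 0L) {
    stopf("base_overlap_fraction: empty query set (fraction undefined)")
  }
  q <- GenomicRanges::reduce(GenomicRanges::granges(query), ignore.strand = TRUE)
  f <- GenomicRanges::reduce(GenomicRanges::granges(features), ignore.strand = TRUE)
  ov <- GenomicRanges::intersect(q, f, ignore.strand = TRUE)
  sum(as.numeric(GenomicRanges::width(ov))) /
    sum(as.numeric(GenomicRanges::width(q)))
}
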
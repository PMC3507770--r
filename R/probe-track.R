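#' Read a probe-level log-ratio track
#'
#' Reads a 4-column bedGraph-like tab-delimited file (chrom, start, end,
#' value; coordinates 0-based half-open, as written by array-processing
#' pipelines) into a probe track: a `GRanges` sorted by position with one
#' `score` per probe holding the log2(ChIP/Input) ratio.  Coordinates are
#' converted to the 1-based closed convention GRanges uses; writers convert
#' back, so files round-trip exactly.
#'
#' @param path path to the tab-delimited file.
#' @param layout [GenomeInfoDb::Seqinfo] layout; probes on chromosomes absent
#'   from the layout, or outside its bounds, are rejected.
#' @return A `GRanges` probe track with numeric `score` metadata column.
#' @export
read_probe_track <- function(path, layout) {
  if (!file.exists(path)) stopf("probe track file not found: %s", path)
  if (file.size(path) == 0L) {
    return(probe_track(character(), integer(), integer(), numeric(), layout))
  }
  dt <- data.table::fread(path, header = FALSE, sep = "\t", fill = TRUE,
                          colClasses = list(character = 1))
  if (nrow(dt) == 0L) {
    return(probe_track(character(), integer(), integer(), numeric(), layout))
  }
  if (ncol(dt) < 4L) stopf("%s: expected 4 tab-delimited columns", path)
  start0 <- suppressWarnings(as.numeric(dt[[2]]))
  end0 <- suppressWarnings(as.numeric(dt[[3]]))
  value <- suppressWarnings(as.numeric(dt[[4]]))
  bad <- which(!is.finite(start0) | !is.finite(end0) | !is.finite(value))
  if (length(bad)) {
    stopf("%s: malformed line %d (non-numeric start/end/value)", path, bad[1])
  }
  bad <- which(start0 >= end0 | start0 < 0)
  if (length(bad)) {
    stopf("%s: line %d: invalid interval [%s, %s)", path, bad[1],
          format(start0[bad[1]], scientific = FALSE),
          format(end0[bad[1]], scientific = FALSE))
  }
  probe_track(dt[[1]], start0, end0, value, layout, src = path)
}

#' Construct a probe track from vectors
#'
#' @param chrom chromosome name per probe.
#' @param start0,end0 probe coordinates, 0-based half-open (file convention).
#' @param value log2(ChIP/Input) ratio per probe.
#' @param layout [GenomeInfoDb::Seqinfo] layout.
#' @param src optional source label used in error messages.
#' @return A sorted `GRanges` probe track with `score` column.
#' @export
probe_track <- function(chrom, start0, end0, value, layout, src = "probe track") {
  known <- GenomeInfoDb::seqnames(layout)
  bad <- which(!(chrom %in% known))
  if (length(bad)) {
    stopf("%s: line %d: chromosome %s not in layout", src, bad[1], chrom[bad[1]])
  }
  lens <- GenomeInfoDb::seqlengths(layout)[chrom]
  bad <- which(end0 > lens)
  if (length(bad)) {
    stopf("%s: line %d: end %s beyond chromosome end", src, bad[1],
          format(end0[bad[1]], scientific = FALSE))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = factor(chrom, levels = known),
    ranges = IRanges::IRanges(start = as.integer(start0) + 1L,
                              end = as.integer(end0)),
    score = as.numeric(value),
    seqinfo = layout)
  GenomicRanges::sort(gr, ignore.strand = TRUE)
}

#' Write a probe track as a bedGraph-like file
#'
#' @param track probe track `GRanges` with `score`.
#' @param path output path; tab-delimited chrom/start/end/value, 0-based
#'   half-open.
#' @export
write_probe_track <- function(track, path) {
  dt <- data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(track)),
    start = GenomicRanges::start(track) - 1L,
    end = GenomicRanges::end(track),
    value = GenomicRanges::score(track))
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

# check a GRanges is a valid probe track: sorted, finite scores
validate_probe_track <- function(track, what = "track") {
  if (!methods::is(track, "GRanges") || is.null(track$score)) {
    stopf("%s must be a GRanges with a 'score' column", what)
  }
  if (length(track) && any(!is.finite(track$score))) {
    stopf("%s has non-finite probe values", what)
  }
  if (S4Vectors::isSorted(track)) track else
    GenomicRanges::sort(track, ignore.strand = TRUE)
}

#' Probe-covered universe of a track
#'
#' The union of array-tiled regions: probe intervals merged, bridging gaps up
#' to `max_gap_bp` (gaps between adjacent probes on a regular array design are
#' part of the tiled region; larger gaps are untiled sequence).
#'
#' @param track probe track `GRanges`.
#' @param max_gap_bp gaps up to this size are bridged (default 1000).
#' @return A `GRanges` of tiled regions.
#' @export
probe_universe <- function(track, max_gap_bp = 1000) {
  GenomicRanges::reduce(GenomicRanges::granges(track),
                        min.gapwidth = max_gap_bp + 1L)
}
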
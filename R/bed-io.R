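#' Read and write BED interval sets
#'
#' Thin wrappers around [rtracklayer::import.bed()] / [rtracklayer::export.bed()]
#' that attach a layout and a set name.  Files are standard BED3+ (0-based
#' half-open); no 1-based auto-detection is attempted.  Coordinates round-trip
#' exactly through a write/read cycle.
#'
#' @param path path to a BED file.
#' @param layout optional [GenomeInfoDb::Seqinfo]; when given, intervals are
#'   validated against it.
#' @param name label stored in `metadata(x)$name`.
#' @return `read_bed`: a sorted `GRanges`.
#' @export
read_bed <- function(path, layout = NULL, name = basename(path)) {
  if (!file.exists(path)) stopf("BED file not found: %s", path)
  gr <- rtracklayer::import(path, format = "BED")
  GenomicRanges::strand(gr) <- "*"
  if (!is.null(layout)) {
    bad <- !(as.character(GenomicRanges::seqnames(gr)) %in%
               GenomeInfoDb::seqnames(layout))
    if (any(bad)) {
      stopf("%s: chromosome %s not in layout", path,
            as.character(GenomicRanges::seqnames(gr))[which(bad)[1]])
    }
    GenomeInfoDb::seqlevels(gr) <- GenomeInfoDb::seqnames(layout)
    GenomeInfoDb::seqinfo(gr) <- layout
  }
  gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
  S4Vectors::metadata(gr)$name <- name
  gr
}

#' @rdname read_bed
#' @param x a `GRanges` to write; `name` and `score` metadata columns, when
#'   present, are emitted as BED columns 4-5.
#' @return `write_bed`: the path, invisibly.
#' @export
write_bed <- function(x, path) {
  rtracklayer::export(x, path, format = "BED")
  invisible(path)
}
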
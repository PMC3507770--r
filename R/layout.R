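#' Define a genome layout (chromosome names and lengths)
#'
#' A layout fixes the coordinate frame for every interval set and probe track
#' in an analysis, in the style of an hg18-like assembly description.  It is
#' represented as a [GenomeInfoDb::Seqinfo] object so that all
#' GenomicRanges operations respect chromosome bounds.
#'
#' @param chrom_names character vector of unique chromosome names.
#' @param chrom_lengths integer vector of chromosome lengths in bp (> 0),
#'   parallel to `chrom_names`.
#' @return A [GenomeInfoDb::Seqinfo] object.
#' @examples
#' genome_layout(c("chr1", "chr2"), c(1e6, 5e5))
#' @export
genome_layout <- function(chrom_names, chrom_lengths) {
  if (length(chrom_names) == 0L) {
    stopf("layout needs at least one chromosome")
  }
  if (length(chrom_names) != length(chrom_lengths)) {
    stopf("chrom_names and chrom_lengths differ in length")
  }
  if (anyDuplicated(chrom_names)) {
    stopf("chromosome names must be unique")
  }
  chrom_lengths <- as.numeric(chrom_lengths)
  if (any(!is.finite(chrom_lengths)) || any(chrom_lengths <= 0)) {
    stopf("chromosome lengths must be positive")
  }
  GenomeInfoDb::Seqinfo(seqnames = as.character(chrom_names),
                        seqlengths = as.integer(chrom_lengths))
}

#' Read a chromosome-sizes file
#'
#' Two-column tab-delimited file: chromosome name, length in bp (the standard
#' `chrom.sizes` format).
#'
#' @param path path to the file.
#' @return A [GenomeInfoDb::Seqinfo] layout.
#' @export
read_chrom_sizes <- function(path) {
  if (!file.exists(path)) stopf("chrom sizes file not found: %s", path)
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          colClasses = list(character = 1))
  if (ncol(dt) < 2L) stopf("chrom sizes file needs 2 columns: %s", path)
  genome_layout(dt[[1]], as.numeric(dt[[2]]))
}

#' Whole-genome interval set for a layout
#'
#' @param layout a [GenomeInfoDb::Seqinfo] layout.
#' @return A `GRanges` with one range spanning each chromosome.
#' @export
layout_ranges <- function(layout) {
  GenomicRanges::GRanges(
    seqnames = GenomeInfoDb::seqnames(layout),
    ranges = IRanges::IRanges(start = 1L,
                              end = GenomeInfoDb::seqlengths(layout)),
    seqinfo = layout)
}

# total bp in a layout
layout_size <- function(layout) {
  sum(as.numeric(GenomeInfoDb::seqlengths(layout)))
}
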
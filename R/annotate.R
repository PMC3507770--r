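#' Read gene models and derive strand-aware TSS positions
#'
#' Accepts a refFlat-like tab-delimited file with columns gene, chrom,
#' strand, txStart, txEnd (coordinates 0-based half-open).  The TSS is the
#' strand-aware 5' end: txStart for `+` genes, txEnd for `-` genes.
#'
#' @param path path to the gene table.
#' @param layout optional [GenomeInfoDb::Seqinfo] for validation.
#' @return A width-1 `GRanges` of TSS positions with a `gene` column.
#' @export
read_gene_models <- function(path, layout = NULL) {
  if (!file.exists(path)) stopf("gene model file not found: %s", path)
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          col.names = c("gene", "chrom", "strand",
                                        "txStart", "txEnd")[1:5])
  tss_granges(dt$gene, dt$chrom, dt$strand, dt$txStart, dt$txEnd, layout)
}

#' Build TSS positions from gene model vectors
#'
#' @param gene,chrom,strand,tx_start0,tx_end0 parallel vectors; coordinates
#'   0-based half-open.
#' @param layout optional layout.
#' @return A width-1 `GRanges` with a `gene` column.
#' @export
tss_granges <- function(gene, chrom, strand, tx_start0, tx_end0,
                        layout = NULL) {
  if (!all(strand %in% c("+", "-"))) stopf("strand must be + or -")
  tss1 <- ifelse(strand == "+", tx_start0 + 1, tx_end0)  # 1-based position
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = as.integer(tss1), width = 1L),
    strand = strand, gene = as.character(gene))
  if (!is.null(layout)) {
    GenomeInfoDb::seqlevels(gr) <- GenomeInfoDb::seqnames(layout)
    GenomeInfoDb::seqinfo(gr) <- layout
  }
  GenomicRanges::sort(gr, ignore.strand = TRUE)
}

#' Fraction of islands containing a TSS, and the associated genes
#'
#' An island overlaps a TSS when the TSS point (widened by `slop_bp` on each
#' side) lies within the island interval; half-open boundary semantics are
#' inherited from the interval model, so a TSS at an island's end coordinate
#' + 1 does not count.
#'
#' @param eis nonempty island `GRanges`.
#' @param tss width-1 TSS `GRanges` with `gene` column (see
#'   [read_gene_models()]).
#' @param slop_bp symmetric slop added to each TSS point (default 0).
#' @return A list with `fraction` (islands containing >= 1 TSS) and `genes`
#'   (deduplicated associated gene ids).
#' @export
associate_tss <- function(eis, tss, slop_bp = 0L) {
  if (length(eis) == 0L) stopf("associate_tss: empty island set")
  pts <- if (slop_bp > 0) {
    GenomicRanges::resize(tss, width = 2L * slop_bp + 1L, fix = "center")
  } else {
    tss
  }
  hit_ei <- IRanges::overlapsAny(eis, pts, ignore.strand = TRUE)
  hit_tss <- IRanges::overlapsAny(pts, eis, ignore.strand = TRUE)
  list(fraction = mean(hit_ei),
       genes = unique(tss$gene[hit_tss]))
}

#' Cross-cell-type island set comparison (Venn-style membership counts)
#'
#' An island of one set is "shared" with another set when it overlaps (>= 1
#' bp) any island of that set.  Because overlap is not transitive, counts
#' are reported set-relative: for each input set, its islands are classified
#' by which of the other sets they overlap, and the per-class counts are
#' returned for that set.
#'
#' @param sets named list of 2 or more island `GRanges` on one layout.
#' @return A [tibble::tibble] with columns `set`, `class` (e.g.
#'   `"A&B"`, `"A-only"`) and `n`; per-set class counts sum to that set's
#'   size.
#' @export
compare_ei_sets <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 2L)
  if (is.null(names(sets)) || any(names(sets) == "")) {
    names(sets) <- LETTERS[seq_along(sets)]
  }
  nm <- names(sets)
  out <- lapply(seq_along(sets), function(i) {
    a <- sets[[i]]
    if (length(a) == 0L) {
      return(tibble::tibble(set = character(0), class = character(0),
                            n = integer(0)))
    }
    memb <- vapply(seq_along(sets), function(j) {
      if (j == i) rep(TRUE, length(a))
      else IRanges::overlapsAny(a, sets[[j]], ignore.strand = TRUE)
    }, logical(length(a)))
    memb <- matrix(memb, nrow = length(a))
    cls <- apply(memb, 1L, function(m) {
      who <- nm[m]
      if (length(who) == 1L) paste0(who, "-only") else paste(who, collapse = "&")
    })
    tb <- table(cls)
    tibble::tibble(set = nm[i], class = names(tb), n = as.integer(tb))
  })
  do.call(rbind, out)
}

#' Stratify genes by island / LOCK / outside status of their TSS
#'
#' Categories are decided on the TSS point and are mutually exclusive and
#' exhaustive: `"EI"` when the TSS lies inside an island (islands are inside
#' LOCKs, so this takes precedence), `"LOCK-not-EI"` when it lies in a LOCK
#' but not in an island, `"non-LOCK"` otherwise.  Genes absent from the
#' expression table are excluded with a message stating the count.
#'
#' @param tss width-1 TSS `GRanges` with `gene` column.
#' @param locks LOCK `GRanges`.
#' @param eis island `GRanges`.
#' @param expr named numeric vector or two-column data frame
#'   (gene, expression); values >= 0 (RPKM-like).
#' @return A [tibble::tibble] with `gene`, `category`, `expression`;
#'   `attr(x, "n_excluded")` counts genes without expression values.
#' @export
stratify_genes <- function(tss, locks, eis, expr) {
  if (is.data.frame(expr)) {
    expr <- stats::setNames(as.numeric(expr[[2]]), as.character(expr[[1]]))
  }
  if (any(expr < 0, na.rm = TRUE)) stopf("expression values must be >= 0")
  in_ei <- IRanges::overlapsAny(tss, eis, ignore.strand = TRUE)
  in_lock <- IRanges::overlapsAny(tss, locks, ignore.strand = TRUE)
  category <- ifelse(in_ei, "EI", ifelse(in_lock, "LOCK-not-EI", "non-LOCK"))
  e <- expr[tss$gene]
  keep <- !is.na(e)
  n_excl <- sum(!keep)
  if (n_excl > 0) {
    message(sprintf("stratify_genes: %d gene(s) without expression values excluded",
                    n_excl))
  }
  out <- tibble::tibble(gene = tss$gene[keep], category = category[keep],
                        expression = unname(e[keep]))
  attr(out, "n_excluded") <- n_excl
  out
}

#' Average signal profile around island midpoints
#'
#' Each anchor's midpoint defines position 0; probes whose midpoints fall
#' within `flank_bp` of it are assigned to `n_bins` equal-width bins and the
#' per-bin mean over all anchors is returned.  Bins containing no probes are
#' reported as `NA`.
#'
#' @param anchors nonempty `GRanges` of anchor intervals (e.g. islands).
#' @param track probe track `GRanges` (any signal: H3K9me2, nucleosome
#'   density, ...).
#' @param flank_bp half-width of the profiled window (default 50,000).
#' @param n_bins number of bins across the 2 * `flank_bp` window (default 50).
#' @return A [tibble::tibble] with `bin`, `rel_center` (bp offset of the bin
#'   center from the anchor midpoint), `mean_signal`, `n_probes`.
#' @export
meta_profile <- function(anchors, track, flank_bp = 50000, n_bins = 50L) {
  if (length(anchors) == 0L) stopf("meta_profile: empty anchor set")
  stopifnot(is_count(flank_bp), is_count(n_bins))
  mid <- (GenomicRanges::start(anchors) + GenomicRanges::end(anchors)) / 2
  win <- GenomicRanges::GRanges(
    seqnames = GenomicRanges::seqnames(anchors),
    ranges = IRanges::IRanges(start = pmax(1, floor(mid - flank_bp)),
                              end = ceiling(mid + flank_bp)))
  GenomeInfoDb::seqlevels(win) <- GenomeInfoDb::seqlevels(track)
  hits <- GenomicRanges::findOverlaps(win, track, ignore.strand = TRUE)
  a <- S4Vectors::queryHits(hits)
  p <- S4Vectors::subjectHits(hits)
  pmid <- (GenomicRanges::start(track)[p] + GenomicRanges::end(track)[p]) / 2
  rel <- pmid - mid[a]
  keep <- abs(rel) <= flank_bp
  rel <- rel[keep]
  val <- track$score[p[keep]]
  binw <- 2 * flank_bp / n_bins
  bin <- pmin(n_bins, pmax(1, floor((rel + flank_bp) / binw) + 1))
  ms <- tapply(val, factor(bin, levels = seq_len(n_bins)), mean)
  np <- tapply(val, factor(bin, levels = seq_len(n_bins)), length)
  tibble::tibble(
    bin = seq_len(n_bins),
    rel_center = -flank_bp + (seq_len(n_bins) - 0.5) * binw,
    mean_signal = as.numeric(ms),
    n_probes = ifelse(is.na(np), 0L, as.integer(np)))
}
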
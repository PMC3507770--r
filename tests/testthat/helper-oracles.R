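# Independent brute-force oracles.  These deliberately avoid the package's
# code paths (and GenomicRanges where feasible) so agreement is evidence,
# not tautology.

# O(n^2) windowed mean over probe midpoints
bf_smooth <- function(start, end, values, window_bp) {
  mid <- (start + end) / 2
  vapply(seq_along(values), function(i) {
    mean(values[abs(mid - mid[i]) <= window_bp / 2])
  }, numeric(1))
}

# all-pairs interval-overlap fraction on plain vectors
bf_interval_frac <- function(qs, qe, fs, fe) {
  hit <- vapply(seq_along(qs), function(i) {
    any(fs <= qe[i] & fe >= qs[i])
  }, logical(1))
  mean(hit)
}

# per-base boolean-mask base-overlap fraction (single chromosome)
bf_base_frac <- function(qs, qe, fs, fe, chrom_len) {
  qmask <- logical(chrom_len)
  fmask <- logical(chrom_len)
  for (i in seq_along(qs)) qmask[qs[i]:qe[i]] <- TRUE
  for (i in seq_along(fs)) fmask[fs[i]:fe[i]] <- TRUE
  sum(qmask & fmask) / sum(qmask)
}

# sequential run/merge/filter enumeration for domain calling on one
# chromosome: flags -> maximal runs -> gap merge -> edge trim -> length and
# enrichment filters.  Written as a plain loop, unlike the vectorized
# implementation.
bf_domains <- function(start, end, flag, merge_gap_bp, min_length_bp,
                       gap_strict = FALSE, min_probes = 0,
                       edge_min = 1, min_flag_frac = 0) {
  runs <- list()
  i <- 1
  n <- length(flag)
  while (i <= n) {
    if (flag[i]) {
      j <- i
      while (j < n && flag[j + 1]) j <- j + 1
      runs[[length(runs) + 1]] <- c(i, j)
      i <- j + 1
    } else i <- i + 1
  }
  if (!length(runs)) return(data.frame(first = integer(0), last = integer(0)))
  groups <- list(list(runs[[1]]))
  for (r in runs[-1]) {
    prev <- groups[[length(groups)]]
    gap <- start[r[1]] - end[prev[[length(prev)]][2]] - 1
    joined <- if (gap_strict) gap < merge_gap_bp else gap <= merge_gap_bp
    if (joined) {
      groups[[length(groups)]] <- c(prev, list(r))
    } else {
      groups[[length(groups) + 1]] <- list(r)
    }
  }
  out <- data.frame(first = integer(0), last = integer(0))
  for (g in groups) {
    while (length(g) && (g[[1]][2] - g[[1]][1] + 1) < edge_min) g <- g[-1]
    while (length(g) && (g[[length(g)]][2] - g[[length(g)]][1] + 1) < edge_min) {
      g <- g[-length(g)]
    }
    if (!length(g)) next
    f <- g[[1]][1]; l <- g[[length(g)]][2]
    len <- end[l] - start[f] + 1
    np <- l - f + 1
    if (len < min_length_bp || np < min_probes) next
    if (min_flag_frac > 0 && mean(flag[f:l]) < min_flag_frac) next
    out <- rbind(out, data.frame(first = f, last = l))
  }
  out
}

# quick GRanges fixture on one or more chromosomes
random_granges <- function(n, layout, min_w = 50, max_w = 5000) {
  chroms <- GenomeInfoDb::seqnames(layout)
  lens <- GenomeInfoDb::seqlengths(layout)
  ch <- sample(chroms, n, replace = TRUE)
  w <- sample(min_w:max_w, n, replace = TRUE)
  s <- vapply(seq_len(n), function(i) sample.int(lens[[ch[i]]] - w[i], 1),
              integer(1))
  GenomicRanges::GRanges(ch, IRanges::IRanges(start = s, width = w),
                         seqinfo = layout)
}

# evenly spaced probe track with the given values
make_track <- function(values, layout, spacing = 200, chrom = "chr1",
                       probe_len = 50) {
  n <- length(values)
  start0 <- seq(0, by = spacing, length.out = n)
  probe_track(rep(chrom, n), start0, start0 + probe_len, values, layout)
}
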
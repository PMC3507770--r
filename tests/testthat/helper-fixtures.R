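# deterministic multi-LOCK fixture: n_locks domains of lock_len bp on one
# chromosome, constant in-LOCK signal, optional dips (start offsets are
# relative to each LOCK start)
ei_fixture <- function(n_locks = 20, lock_len = 1e5, spacing = 200,
                       base = 1.5, gap = 5e4,
                       dips = list(), noise_sd = 0, seed = 1) {
  chrom_len <- n_locks * (lock_len + gap) + gap
  lay <- genome_layout("chr1", chrom_len)
  set.seed(seed)
  starts0 <- seq(0, chrom_len - 100, by = spacing)
  v <- rnorm(length(starts0), 0, max(noise_sd, 1e-12)) * (noise_sd > 0)
  tr <- probe_track(rep("chr1", length(starts0)), starts0, starts0 + 50,
                    v, lay)
  lock_s <- gap + (seq_len(n_locks) - 1) * (lock_len + gap) + 1
  locks <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(start = lock_s, width = lock_len), seqinfo = lay)
  mid <- (GenomicRanges::start(tr) + GenomicRanges::end(tr)) / 2
  in_lock <- IRanges::overlapsAny(
    GenomicRanges::GRanges("chr1", IRanges::IRanges(floor(mid), width = 1)),
    locks)
  tr$score <- tr$score + ifelse(in_lock, base, 0)
  dip_gr <- NULL
  for (d in dips) {
    ds <- lock_s[d$lock] + d$offset
    de <- ds + d$len - 1
    sel <- mid >= ds & mid <= de
    tr$score[sel] <- tr$score[sel] - d$depth
    dg <- GenomicRanges::GRanges("chr1", IRanges::IRanges(ds, de),
                                 seqinfo = lay)
    dip_gr <- if (is.null(dip_gr)) dg else c(dip_gr, dg)
  }
  list(track = tr, locks = locks, dips = dip_gr, layout = lay)
}
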
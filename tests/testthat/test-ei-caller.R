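test_that("a constant-signal LOCK yields zero islands", {
  fx <- ei_fixture(n_locks = 5)
  eis <- detect_eis(fx$track, fx$locks)
  expect_length(eis, 0L)
})

test_that("empty LOCK set gives an empty island set, not an error", {
  fx <- ei_fixture(n_locks = 2)
  eis <- detect_eis(fx$track, fx$locks[0])
  expect_length(eis, 0L)
  expect_s4_class(eis, "GRanges")
})

test_that("a planted dip is found as exactly one island matching the run oracle", {
  fx <- ei_fixture(n_locks = 10, noise_sd = 0.3,
                   dips = list(list(lock = 7, offset = 47000, len = 6000,
                                    depth = 2.0 * 0.3)))
  # dip depth scaled in units of the noise SD (2 SD), centered at 50 kb
  eis <- detect_eis(fx$track, fx$locks)
  expect_length(eis, 1L)
  dip_mid <- (GenomicRanges::start(fx$dips) + GenomicRanges::end(fx$dips)) / 2
  expect_true(GenomicRanges::start(eis) <= dip_mid &&
                GenomicRanges::end(eis) >= dip_mid)
  # edges within half a smoothing window of the planted dip
  expect_lt(abs(GenomicRanges::start(eis) - GenomicRanges::start(fx$dips)),
            2500)
  expect_lt(abs(GenomicRanges::end(eis) - GenomicRanges::end(fx$dips)), 2500)
  expect_equal(eis$parent_lock, 7L)

  # independent enumeration of sub-threshold runs at the computed threshold
  t_val <- S4Vectors::metadata(eis)$threshold
  hits <- GenomicRanges::findOverlaps(fx$track, fx$locks)
  p <- S4Vectors::queryHits(hits)
  sm <- numeric(length(p))
  for (l in unique(S4Vectors::subjectHits(hits))) {
    sel <- S4Vectors::subjectHits(hits) == l
    sm[sel] <- bf_smooth(GenomicRanges::start(fx$track)[p[sel]],
                         GenomicRanges::end(fx$track)[p[sel]],
                         fx$track$score[p[sel]], 5000)
  }
  bf <- bf_domains(GenomicRanges::start(fx$track)[p],
                   GenomicRanges::end(fx$track)[p],
                   (t_val - sm) > 1e-9, 1000, 1000, gap_strict = TRUE, min_probes = 10)
  # margin filter by hand
  keep <- vapply(seq_len(nrow(bf)), function(i) {
    s <- GenomicRanges::start(fx$track)[p[bf$first[i]]]
    e <- GenomicRanges::end(fx$track)[p[bf$last[i]]]
    li <- S4Vectors::subjectHits(hits)[bf$first[i]]
    s - GenomicRanges::start(fx$locks)[li] >= 20000 &&
      GenomicRanges::end(fx$locks)[li] - e >= 20000
  }, logical(1))
  bf <- bf[keep, , drop = FALSE]
  expect_equal(nrow(bf), 1L)
  expect_equal(GenomicRanges::start(eis),
               GenomicRanges::start(fx$track)[p[bf$first]])
  expect_equal(GenomicRanges::end(eis),
               GenomicRanges::end(fx$track)[p[bf$last]])
})

test_that("dips inside the boundary margin are rejected", {
  fx <- ei_fixture(n_locks = 10, noise_sd = 0.3,
                   dips = list(list(lock = 4, offset = 10000, len = 6000,
                                    depth = 0.6)))
  eis <- detect_eis(fx$track, fx$locks)
  expect_length(eis, 0L)
})

test_that("island invariants hold by construction on noisy synthetic genomes", {
  for (seed in 1:3) {
    sim <- simulate_track(sim_spec(), seed = seed)
    locks <- call_locks(sim$track)
    params <- ei_params()
    eis <- detect_eis(sim$track, locks, params)
    if (length(eis) == 0) next
    expect_true(all(GenomicRanges::width(eis) >= params$min_length_bp))
    expect_true(all(eis$n_probes >= params$min_probes))
    left <- GenomicRanges::start(eis) -
      GenomicRanges::start(locks)[eis$parent_lock]
    right <- GenomicRanges::end(locks)[eis$parent_lock] -
      GenomicRanges::end(eis)
    expect_true(all(left >= params$boundary_margin_bp))
    expect_true(all(right >= params$boundary_margin_bp))
    # disjoint and separated by at least the merge gap within a LOCK
    by_lock <- split(eis, eis$parent_lock)
    for (g in by_lock) {
      if (length(g) < 2) next
      gaps <- GenomicRanges::start(g)[-1] -
        GenomicRanges::end(g)[-length(g)] - 1
      expect_true(all(gaps >= params$merge_gap_bp))
    }
    expect_true(all(eis$min_smoothed < S4Vectors::metadata(eis)$threshold))
  }
})

test_that("island detection is deterministic and percentile-monotone", {
  sim <- simulate_track(sim_spec(), seed = 31)
  locks <- call_locks(sim$track)
  a <- detect_eis(sim$track, locks)
  b <- detect_eis(sim$track, locks)
  expect_identical(GenomicRanges::start(a), GenomicRanges::start(b))
  expect_identical(a$min_smoothed, b$min_smoothed)
  # lowering the percentile lowers the threshold (never more sub-threshold probes)
  th <- vapply(c(0.05, 0.02, 0.01, 0.005), function(q) {
    S4Vectors::metadata(
      detect_eis(sim$track, locks, ei_params(low_percentile = q)))$threshold
  }, numeric(1))
  expect_true(all(diff(th) <= 0))
})

test_that("island summaries and concordance behave", {
  lay <- genome_layout("chr1", 1e6)
  g <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(start = c(1000, 50000), width = c(4000, 6000)),
    seqinfo = lay)
  g$parent_lock <- c(1L, 1L)
  s <- ei_summary(g)
  expect_equal(s$n, 2L)
  expect_equal(s$mean_size_bp, 5000)
  expect_equal(ei_summary(g[0])$n, 0L)
  expect_equal(ei_concordance(g, g), 1.0)
  far <- GenomicRanges::shift(g, 500000)
  expect_equal(ei_concordance(g, far), 0.0)
  expect_error(ei_concordance(g[0], g), "empty")
})

test_that("island calls from two noise replicates of one truth concur", {
  truth <- simulate_truth(sim_spec(ei = list(depth = 2.0)), seed = 11)
  call_rep <- function(noise_seed) {
    tr <- simulate_signal(truth, seed = noise_seed)
    detect_eis(tr, call_locks(tr))
  }
  a <- call_rep(101)
  b <- call_rep(202)
  expect_gte(ei_concordance(a, b), 0.8)
  expect_gte(ei_concordance(b, a), 0.8)
})
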
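lay_e <- genome_layout("chr1", 1e6)
gr1 <- function(s, e) GenomicRanges::GRanges("chr1",
  IRanges::IRanges(start = s, end = e), seqinfo = lay_e)

test_that("sampled null sets match query lengths exactly and place uniformly", {
  uni <- gr1(1, 1e6)
  q <- gr1(c(1000, 50000), c(4999, 55999))  # lengths 4000, 6000
  set.seed(41)
  for (i in 1:50) {
    s <- sample_matched(q, uni)
    expect_setequal(GenomicRanges::width(s), c(4000, 6000))
  }
  # uniformity of a single 5 kb interval over one segment: chi-square on 20 bins
  set.seed(42)
  segs <- eislands:::universe_segments(uni)
  starts <- vapply(1:10000, function(i) {
    eislands:::place_matched(5000, segs)$start
  }, numeric(1))
  expect_true(all(starts >= 1 & starts <= 995001))
  h <- table(cut(starts, breaks = seq(0, 995001, length.out = 21)))
  expect_gt(chisq.test(h)$p.value, 0.001)
})

test_that("segments are chosen proportionally to their valid start counts", {
  uni <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(start = c(1, 950001), width = c(900000, 50000)),
    seqinfo = lay_e)
  segs <- eislands:::universe_segments(uni)
  set.seed(43)
  picks <- vapply(1:50000, function(i) {
    eislands:::place_matched(10000, segs)$start < 950001
  }, logical(1))
  share <- (900000 - 10000 + 1) / ((900000 - 10000 + 1) + (50000 - 10000 + 1))
  expect_lt(abs(mean(picks) - share), 0.01)
})

test_that("infeasible and congested sampling fail with clear messages", {
  uni <- gr1(1, 20000)
  expect_error(sample_matched(gr1(1, 50000), uni), "longer than every")
  # 3 disjoint 9 kb intervals cannot fit a 20 kb segment
  q <- gr1(c(1, 1, 1), c(9000, 9000, 9000))
  expect_error(sample_matched(q, uni, max_attempts = 50), "allow_overlap")
})

test_that("degenerate enrichment cases follow the stated rules", {
  q <- gr1(c(10000, 200000), c(14999, 204999))
  uni <- gr1(1, 1e6)
  full <- gr1(1, 1e6)
  p <- enrich_params(n_permutations = 100, seed = 7)
  r <- permutation_enrichment(q, full, uni, p)
  expect_equal(r$observed, 1.0)
  expect_equal(r$null_mean, 1.0)
  expect_equal(r$fold, 1.0)
  expect_equal(r$p_raw, 1.0)
  r0 <- permutation_enrichment(q, full[0], uni, p)
  expect_equal(r0$observed, 0)
  expect_equal(r0$fold, 1)  # 0/0 rule
  expect_equal(r0$p_raw, 1.0)
  expect_error(permutation_enrichment(q[0], full, uni, p), "empty")
  expect_error(enrich_params(n_permutations = 50), "at least 100")
})

test_that("enrichment runs are bit-reproducible given a seed", {
  set.seed(99)
  q <- GenomicRanges::reduce(random_granges(20, lay_e, min_w = 2000,
                                            max_w = 6000))
  f <- random_granges(100, lay_e, min_w = 500, max_w = 2000)
  uni <- gr1(1, 1e6)
  p <- enrich_params(n_permutations = 200, seed = 123)
  r1 <- permutation_enrichment(q, f, uni, p)
  r2 <- permutation_enrichment(q, f, uni, p)
  expect_identical(r1, r2)
  # and the RNG stream of the caller is untouched
  s1 <- .Random.seed
  permutation_enrichment(q, f, uni, p)
  expect_identical(s1, .Random.seed)
})

test_that("the null interval statistic agrees with the public overlap functions", {
  set.seed(55)
  f <- random_granges(80, lay_e, min_w = 500, max_w = 3000)
  fidx <- eislands:::feature_index(f)
  q <- GenomicRanges::reduce(random_granges(40, lay_e, min_w = 1000,
                                            max_w = 8000))
  bp <- eislands:::intersect_bp(
    as.character(GenomicRanges::seqnames(q)),
    GenomicRanges::start(q), GenomicRanges::end(q), fidx)
  expect_equal(mean(bp > 0), interval_overlap_fraction(q, f))
  expect_equal(sum(bp) / sum(GenomicRanges::width(q)),
               base_overlap_fraction(q, f))
})

test_that("Bonferroni correction clamps and preserves order", {
  rows <- lapply(c(0.01, 0.5, 0.002), function(p) {
    tibble::tibble(feature = paste0("f", p), statistic = "interval-overlap",
                   observed = 0.5, null_mean = 0.1, null_sd = 0.01,
                   fold = 5, p_raw = p, p_bonferroni = NA_real_,
                   n_permutations = 1000L, seed = 1L)
  })
  adj <- bonferroni_adjust(rows)
  expect_equal(adj$p_bonferroni, c(0.03, 1.0, 0.006))
  expect_equal(adj$feature, c("f0.01", "f0.5", "f0.002"))
  one <- bonferroni_adjust(rows[1])
  expect_equal(one$p_bonferroni, one$p_raw)
})

test_that("domain-level base overlap test recovers designed coincidence", {
  lay <- genome_layout(c("chr1", "chr2"), c(5e6, 5e6))
  # 10 locks of 100 kb; blocks cover exactly the first 80% of each lock
  locks <- GenomicRanges::GRanges(
    rep(c("chr1", "chr2"), each = 5),
    IRanges::IRanges(start = rep(seq(1e5, 4.1e6, by = 1e6), 2), width = 1e5),
    seqinfo = lay)
  blocks <- GenomicRanges::resize(locks, width = 8e4, fix = "start")
  p <- enrich_params(n_permutations = 1000, seed = 17)
  r <- domain_base_overlap_test(locks, blocks, lay, p)
  expect_equal(r$observed, 0.8)
  expect_lte(r$p_raw, 0.002)
  # blocks equal to locks give observed 1
  r2 <- domain_base_overlap_test(locks, locks, lay,
                                 enrich_params(n_permutations = 100, seed = 1))
  expect_equal(r2$observed, 1.0)
})

test_that("null mean approximates block genome fraction for uniform blocks", {
  lay <- genome_layout("chr1", 2e6)
  set.seed(67)
  blocks <- GenomicRanges::reduce(random_granges(60, lay, min_w = 5000,
                                                 max_w = 15000))
  f <- sum(as.numeric(GenomicRanges::width(blocks))) / 2e6
  locks <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(start = c(2e5, 9e5, 15e5), width = 1e5), seqinfo = lay)
  r <- domain_base_overlap_test(locks, blocks, lay,
                                enrich_params(n_permutations = 500, seed = 3))
  expect_lt(abs(r$null_mean - f), 0.03)
})
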
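lay_a <- genome_layout("chr1", 1e6)

test_that("TSS association uses strand-aware points and half-open bounds", {
  # EI spans file coords [100, 5100) -> internal 101..5100
  ei <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 5100),
                               seqinfo = lay_a)
  tss <- tss_granges(c("gA", "gB", "gC"), rep("chr1", 3), c("+", "+", "-"),
                     tx_start0 = c(2000, 5100, 8000),
                     tx_end0 = c(3000, 6000, 9000), layout = lay_a)
  res <- associate_tss(ei, tss)
  expect_equal(res$fraction, 1.0)      # gA's TSS at 2001 is inside
  expect_equal(res$genes, "gA")        # gB sits exactly at the exclusive end
  expect_error(associate_tss(ei[0], tss), "empty")

  # minus-strand gene: TSS is txEnd
  tssm <- tss_granges("gM", "chr1", "-", 100, 3000, layout = lay_a)
  expect_equal(GenomicRanges::start(tssm), 3000L)
})

test_that("TSS association equals a brute-force point-in-interval scan", {
  set.seed(71)
  eis <- GenomicRanges::reduce(random_granges(100, lay_a, min_w = 1000,
                                              max_w = 8000))
  pos0 <- sample.int(999000, 500)
  tss <- tss_granges(paste0("g", 1:500), rep("chr1", 500),
                     sample(c("+", "-"), 500, TRUE),
                     tx_start0 = pos0, tx_end0 = pos0 + 1000, layout = lay_a)
  res <- associate_tss(eis, tss)
  pts <- GenomicRanges::start(tss)
  hit <- vapply(seq_along(eis), function(i) {
    any(pts >= GenomicRanges::start(eis)[i] & pts <= GenomicRanges::end(eis)[i])
  }, logical(1))
  expect_equal(res$fraction, mean(hit))
})

test_that("cross-set comparison classes are consistent and sum to set sizes", {
  g <- function(s) GenomicRanges::GRanges("chr1",
    IRanges::IRanges(start = s, width = 2000), seqinfo = lay_a)
  ident <- list(A = g(seq(1e4, 1e5, by = 1e4)),
                B = g(seq(1e4, 1e5, by = 1e4)),
                C = g(seq(1e4, 1e5, by = 1e4)))
  v <- compare_ei_sets(ident)
  expect_true(all(v$class == "A&B&C"))
  expect_equal(sum(v$n[v$set == "A"]), 10L)

  disj <- list(A = g(1e4), B = g(5e4), C = g(9e4))
  vd <- compare_ei_sets(disj)
  expect_setequal(vd$class, c("A-only", "B-only", "C-only"))

  set.seed(72)
  rnd <- list(A = GenomicRanges::reduce(random_granges(30, lay_a)),
              B = GenomicRanges::reduce(random_granges(30, lay_a)),
              C = GenomicRanges::reduce(random_granges(30, lay_a)))
  vr <- compare_ei_sets(rnd)
  for (nm in names(rnd)) {
    expect_equal(sum(vr$n[vr$set == nm]), length(rnd[[nm]]))
  }
  # spot-check one class against brute-force pairwise overlap
  ab <- IRanges::overlapsAny(rnd$A, rnd$B)
  ac <- IRanges::overlapsAny(rnd$A, rnd$C)
  expect_equal(sum(vr$n[vr$set == "A" & vr$class == "A-only"]),
               sum(!ab & !ac))
  expect_equal(sum(vr$n[vr$set == "A" & vr$class == "A&B&C"]),
               sum(ab & ac))
})

test_that("gene stratification is an exhaustive partition with EI precedence", {
  locks <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1e5, 5e5),
                                  seqinfo = lay_a)
  eis <- GenomicRanges::GRanges("chr1", IRanges::IRanges(2e5, 2.1e5),
                                seqinfo = lay_a)
  tss <- tss_granges(c("in_ei", "in_lock", "outside", "no_expr"),
                     rep("chr1", 4), rep("+", 4),
                     tx_start0 = c(2.05e5, 3e5, 8e5, 8.5e5),
                     tx_end0 = c(2.06e5, 3.1e5, 8.1e5, 8.6e5),
                     layout = lay_a)
  expr <- c(in_ei = 10, in_lock = 1, outside = 20)
  expect_message(
    st <- stratify_genes(tss, locks, eis, expr),
    "1 gene")
  expect_equal(nrow(st), 3L)
  expect_equal(attr(st, "n_excluded"), 1L)
  expect_equal(st$category[st$gene == "in_ei"], "EI")
  expect_equal(st$category[st$gene == "in_lock"], "LOCK-not-EI")
  expect_equal(st$category[st$gene == "outside"], "non-LOCK")
})

test_that("stratification recovers a designed expression ordering", {
  set.seed(73)
  sim <- simulate_track(sim_spec(), seed = 73)
  locks <- sim$truth$locks
  eis <- sim$truth$eis
  n <- 300
  pos0 <- sort(sample.int(2e7 - 1000, n))
  chrom <- ifelse(pos0 < 1e7, "chr1", "chr2")
  pos0 <- ifelse(pos0 < 1e7, pos0, pos0 - 1e7)
  # put a third of the genes inside islands to populate that class
  k <- min(length(eis), 100)
  pos0[seq_len(k)] <- floor((GenomicRanges::start(eis) +
                               GenomicRanges::end(eis)) / 2)[seq_len(k)]
  chrom[seq_len(k)] <- as.character(GenomicRanges::seqnames(eis))[seq_len(k)]
  tss <- tss_granges(paste0("g", seq_len(n)), chrom, rep("+", n),
                     pos0, pos0 + 500, layout = sim$truth$layout)
  in_ei <- IRanges::overlapsAny(tss, eis)
  in_lock <- IRanges::overlapsAny(tss, locks)
  mu <- ifelse(in_ei, 5, ifelse(in_lock, 0.5, 8))
  expr <- stats::setNames(rgamma(n, shape = 2, scale = mu / 2), tss$gene)
  st <- stratify_genes(tss, locks, eis, expr)
  med <- tapply(st$expression, st$category, median)
  expect_true(med[["non-LOCK"]] > med[["EI"]])
  expect_true(med[["EI"]] > med[["LOCK-not-EI"]])
  expect_equal(nrow(st), n)
})

test_that("meta profiles are flat on constants and dip where planted", {
  tr <- make_track(rep(1.2, 5000), lay_a)
  anchors <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(start = c(2e5, 5e5), width = 5000), seqinfo = lay_a)
  prof <- meta_profile(anchors, tr, flank_bp = 20000, n_bins = 20)
  expect_true(all(abs(prof$mean_signal - 1.2) < 1e-12))
  expect_equal(nrow(prof), 20L)

  # single anchor equals its own binned signal
  one <- meta_profile(anchors[1], tr, flank_bp = 10000, n_bins = 10)
  expect_true(all(abs(one$mean_signal - 1.2) < 1e-12))

  # planted dips produce a central minimum at least half the depth deep
  set.seed(74)
  sim <- simulate_track(sim_spec(), seed = 74)
  eis <- sim$truth$eis
  prof2 <- meta_profile(eis, sim$track, flank_bp = 25000, n_bins = 25)
  central <- prof2$mean_signal[prof2$bin %in% 12:14]
  flank <- prof2$mean_signal[prof2$bin %in% c(1:3, 23:25)]
  expect_lt(min(central), mean(flank) - 2.5 / 2)

  # anchor order does not matter
  perm <- sample(length(eis))
  prof3 <- meta_profile(eis[perm], sim$track, flank_bp = 25000, n_bins = 25)
  expect_equal(prof3$mean_signal, prof2$mean_signal)
})
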
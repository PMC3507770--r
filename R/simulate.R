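#' Specification for synthetic tiling-array data
#'
#' Describes a synthetic genome with planted heterochromatin domains (LOCKs),
#' euchromatin-island dips inside them, and feature sets with designed
#' enrichment, emulating a whole-genome tiling array (~200 bp median probe
#' spacing) measuring log2(ChIP/Input) ratios.
#'
#' @param n_chrom number of chromosomes.
#' @param chrom_length_bp length of each chromosome.
#' @param probe_spacing_bp probe grid spacing (default 200, matching the
#'   ~203 bp median spacing of 2.1M whole-genome designs).
#' @param probe_length_bp probe length (default 50).
#' @param jitter_bp uniform jitter applied to each probe center (+/- 25 bp by
#'   default) so grid positions do not alias with smoothing windows.
#' @param background_mean,noise_sd Gaussian background log-ratio parameters.
#' @param lock list: `coverage` (target genome fraction inside LOCKs),
#'   `shift` (mean log-ratio elevation inside LOCKs, in noise-SD units),
#'   `length_meanlog`/`length_sdlog` (log-normal domain length), `min_gap_bp`
#'   (minimum separation between planted LOCKs).
#' @param ei list: `lambda` (dips per LOCK, Poisson), `length_min`/
#'   `length_max` (uniform dip length, bp), `depth` (mean decrease inside a
#'   dip, noise-SD units), `edge_margin_bp` (minimum dip distance from LOCK
#'   edges), `min_gap_bp` (minimum separation between dips),
#'   `n_margin_dips` (extra dips deliberately planted inside the edge
#'   margin, recorded separately; default 0).
#' @param features list: `p_in_ei` (probability a planted island receives a
#'   centered feature), `background_per_mb` (density of background features),
#'   `length_bp` (feature length).
#' @param seed default RNG seed carried by the spec.
#' @return A `sim_spec` list.
#' @export
sim_spec <- function(n_chrom = 2L, chrom_length_bp = 10e6,
                     probe_spacing_bp = 200L, probe_length_bp = 50L,
                     jitter_bp = 25L,
                     background_mean = 0, noise_sd = 1,
                     lock = list(), ei = list(), features = list(),
                     seed = NULL) {
  lock <- utils::modifyList(list(coverage = 0.40, shift = 1.5,
                                 length_meanlog = log(2e6),
                                 length_sdlog = 0.35,
                                 min_gap_bp = 100000), lock)
  ei <- utils::modifyList(list(lambda = 3, length_min = 3000,
                               length_max = 8000, depth = 2.5,
                               edge_margin_bp = 20000, min_gap_bp = 10000,
                               n_margin_dips = 0L), ei)
  features <- utils::modifyList(list(p_in_ei = 0.5, background_per_mb = 3,
                                     length_bp = 500), features)
  stopifnot(lock$coverage > 0, lock$coverage < 1, ei$depth >= 0,
            features$background_per_mb >= 0,
            features$p_in_ei >= 0, features$p_in_ei <= 1)
  structure(list(n_chrom = as.integer(n_chrom),
                 chrom_length_bp = chrom_length_bp,
                 probe_spacing_bp = probe_spacing_bp,
                 probe_length_bp = probe_length_bp,
                 jitter_bp = jitter_bp,
                 background_mean = background_mean, noise_sd = noise_sd,
                 lock = lock, ei = ei, features = features, seed = seed),
            class = "sim_spec")
}

#' The default demonstration spec
#'
#' Two 10 Mb chromosomes, 40% LOCK coverage, +1.5 SD in-LOCK shift, 3 dips
#' per LOCK of 3-8 kb at 2.5 SD depth, at least 20 kb from LOCK edges.
#' LOCK lengths are log-normal with a 2 Mb median, which keeps planted
#' island bp near 1% of LOCK bp -- the operating regime in which a
#' bottom-percentile threshold can represent all planted islands.
#'
#' @param ... overrides passed to [sim_spec()].
#' @return A `sim_spec` list.
#' @export
demo_sim_spec <- function(...) sim_spec(...)

#' Plant the ground-truth structure of a synthetic genome
#'
#' Draws the probe grid, the LOCK placements (disjoint, log-normal lengths
#' drawn until the target coverage is reached; the final domain is trimmed
#' so planted coverage matches the target), and the island dips inside each
#' LOCK.  The truth is independent of the signal noise: several noise
#' realizations of one truth can be rendered with [simulate_signal()].
#'
#' @param spec a [sim_spec()].
#' @param seed RNG seed (defaults to `spec$seed`).
#' @return A `sim_truth` list: `layout`, `probes` (grid `GRanges`, no
#'   values), `locks`, `eis` (with `parent_lock`, `depth`), `margin_eis`,
#'   and the `spec`.
#' @export
simulate_truth <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "sim_spec"))
  with_seed(seed, {
    layout <- genome_layout(paste0("chr", seq_len(spec$n_chrom)),
                            rep(spec$chrom_length_bp, spec$n_chrom))
    probes <- sim_probe_grid(spec, layout)
    locks <- sim_plant_locks(spec, layout)
    eis <- sim_plant_dips(spec, locks,
                          margin = spec$ei$edge_margin_bp,
                          lambda = spec$ei$lambda)
    margin_eis <- sim_plant_margin_dips(spec, locks)
    structure(list(layout = layout, probes = probes, locks = locks,
                   eis = eis, margin_eis = margin_eis, spec = spec),
              class = "sim_truth")
  })
}

sim_probe_grid <- function(spec, layout) {
  grs <- lapply(GenomeInfoDb::seqnames(layout), function(ch) {
    len <- GenomeInfoDb::seqlengths(layout)[[ch]]
    centers <- seq(spec$probe_spacing_bp %/% 2, len - spec$probe_length_bp,
                   by = spec$probe_spacing_bp)
    if (spec$jitter_bp > 0) {
      centers <- centers + sample.int(2L * spec$jitter_bp + 1L,
                                      length(centers), replace = TRUE) -
        spec$jitter_bp - 1L
    }
    half <- spec$probe_length_bp %/% 2
    s <- pmax(1L, as.integer(centers) - half)
    GenomicRanges::GRanges(ch, IRanges::IRanges(
      start = s, width = spec$probe_length_bp), seqinfo = layout)
  })
  GenomicRanges::sort(do.call(c, grs), ignore.strand = TRUE)
}

sim_plant_locks <- function(spec, layout) {
  target <- spec$lock$coverage * layout_size(layout)
  chroms <- GenomeInfoDb::seqnames(layout)
  lens <- GenomeInfoDb::seqlengths(layout)
  placed <- list()
  total <- 0
  tries <- 0L
  while (total < target) {
    L <- round(stats::rlnorm(1, spec$lock$length_meanlog,
                             spec$lock$length_sdlog))
    # trim the final domain so planted coverage hits the target exactly
    if (total + L > target) L <- max(1, round(target - total))
    ok <- FALSE
    for (att in 1:200) {
      ch <- sample(chroms, 1L)
      if (lens[[ch]] < L + 2) next
      s <- sample.int(lens[[ch]] - L, 1L)
      cand <- c(s - spec$lock$min_gap_bp, s + L - 1 + spec$lock$min_gap_bp)
      clash <- any(vapply(placed, function(p) {
        p$ch == ch && p$s <= cand[2] && p$e >= cand[1]
      }, logical(1)))
      if (!clash) { ok <- TRUE; break }
    }
    if (!ok) {
      tries <- tries + 1L
      if (tries > 50L) {
        stopf("simulate_truth: cannot reach LOCK coverage %.2f on this layout",
              spec$lock$coverage)
      }
      next
    }
    placed[[length(placed) + 1L]] <- list(ch = ch, s = s, e = s + L - 1)
    total <- total + L
  }
  gr <- GenomicRanges::GRanges(
    seqnames = vapply(placed, `[[`, character(1), "ch"),
    ranges = IRanges::IRanges(
      start = vapply(placed, `[[`, numeric(1), "s"),
      end = vapply(placed, `[[`, numeric(1), "e")),
    seqinfo = layout)
  GenomicRanges::sort(gr, ignore.strand = TRUE)
}

# place dips uniformly inside locks, >= margin from edges, pairwise gaps
# >= ei$min_gap_bp; n per lock ~ Poisson(lambda)
sim_plant_dips <- function(spec, locks, margin, lambda) {
  out <- list()
  for (li in seq_along(locks)) {
    n <- stats::rpois(1, lambda)
    if (n == 0) next
    lo <- GenomicRanges::start(locks)[li] + margin
    hi <- GenomicRanges::end(locks)[li] - margin
    placed <- list()
    for (d in seq_len(n)) {
      L <- round(stats::runif(1, spec$ei$length_min, spec$ei$length_max))
      if (hi - L + 1 <= lo) next
      for (att in 1:200) {
        s <- round(stats::runif(1, lo, hi - L + 1))
        e <- s + L - 1
        clash <- any(vapply(placed, function(p) {
          s <= p$e + spec$ei$min_gap_bp && e >= p$s - spec$ei$min_gap_bp
        }, logical(1)))
        if (!clash) {
          placed[[length(placed) + 1L]] <- list(s = s, e = e)
          break
        }
      }
    }
    for (p in placed) {
      out[[length(out) + 1L]] <- list(
        ch = as.character(GenomicRanges::seqnames(locks))[li],
        s = p$s, e = p$e, parent = li)
    }
  }
  dips_to_granges(out, spec, locks)
}

# dips deliberately inside the boundary margin (for margin-filter checks)
sim_plant_margin_dips <- function(spec, locks) {
  n <- spec$ei$n_margin_dips
  out <- list()
  if (n > 0 && length(locks) > 0) {
    for (d in seq_len(n)) {
      li <- sample.int(length(locks), 1L)
      L <- round(stats::runif(1, spec$ei$length_min, spec$ei$length_max))
      off <- round(stats::runif(1, 1000, max(2000, spec$ei$edge_margin_bp - L - 1000)))
      left <- stats::runif(1) < 0.5
      s <- if (left) GenomicRanges::start(locks)[li] + off
           else GenomicRanges::end(locks)[li] - off - L + 1
      out[[length(out) + 1L]] <- list(
        ch = as.character(GenomicRanges::seqnames(locks))[li],
        s = s, e = s + L - 1, parent = li)
    }
  }
  dips_to_granges(out, spec, locks)
}

dips_to_granges <- function(out, spec, locks) {
  if (length(out) == 0L) {
    gr <- GenomicRanges::GRanges(seqinfo = GenomeInfoDb::seqinfo(locks))
    gr$parent_lock <- integer(0)
    gr$depth <- numeric(0)
    return(gr)
  }
  gr <- GenomicRanges::GRanges(
    seqnames = vapply(out, `[[`, character(1), "ch"),
    ranges = IRanges::IRanges(start = vapply(out, `[[`, numeric(1), "s"),
                              end = vapply(out, `[[`, numeric(1), "e")),
    seqinfo = GenomeInfoDb::seqinfo(locks))
  gr$parent_lock <- vapply(out, `[[`, numeric(1), "parent")
  gr$depth <- rep(spec$ei$depth, length(gr))
  GenomicRanges::sort(gr, ignore.strand = TRUE)
}

#' Render a noise realization of a planted truth
#'
#' Probe values are Gaussian around the background mean, elevated by the
#' LOCK shift inside planted LOCKs and decreased by the dip depth inside
#' planted islands (including margin dips); dips are rectangular mean
#' shifts.  Probe membership is decided on the probe midpoint.
#'
#' @param truth a `sim_truth` from [simulate_truth()].
#' @param seed RNG seed for the noise.
#' @return A probe track `GRanges` with `score`.
#' @export
simulate_signal <- function(truth, seed = NULL) {
  stopifnot(inherits(truth, "sim_truth"))
  spec <- truth$spec
  with_seed(seed, {
    track <- truth$probes
    n <- length(track)
    mid <- GenomicRanges::resize(track, width = 1L, fix = "center")
    v <- stats::rnorm(n, spec$background_mean, spec$noise_sd)
    in_lock <- IRanges::overlapsAny(mid, truth$locks, ignore.strand = TRUE)
    v[in_lock] <- v[in_lock] + spec$lock$shift * spec$noise_sd
    all_dips <- c(GenomicRanges::granges(truth$eis),
                  GenomicRanges::granges(truth$margin_eis))
    if (length(all_dips)) {
      in_dip <- IRanges::overlapsAny(mid, all_dips, ignore.strand = TRUE)
      v[in_dip] <- v[in_dip] - spec$ei$depth * spec$noise_sd
    }
    track$score <- v
    track
  })
}

#' Simulate a track and its ground truth in one call
#'
#' @param spec a [sim_spec()].
#' @param seed RNG seed; structure and noise are both derived from it.
#' @return A list with `track` (probe `GRanges` with `score`) and `truth`
#'   (`sim_truth`).
#' @export
simulate_track <- function(spec = sim_spec(), seed = spec$seed) {
  truth <- simulate_truth(spec, seed = seed)
  sig_seed <- if (is.null(seed)) NULL else (seed + 1L) %% .Machine$integer.max
  list(track = simulate_signal(truth, seed = sig_seed), truth = truth)
}

#' Solve for the island-linking probability giving a target fold enrichment
#'
#' Under the closed-form model of [simulate_features()], expected observed
#' overlap is `p + (1 - p) * m_bg` and the expected null mean is
#' `mean(1 - exp(-(d + p n / G)(L + f)))` (background density plus the
#' linked features a random placement can hit).  Solves for `p` such that
#' expected fold equals `target_fold`.
#'
#' @param truth a `sim_truth` with planted islands.
#' @param target_fold desired expected fold enrichment.
#' @param background_per_mb,length_bp feature parameters (defaults from the
#'   truth's spec).
#' @return The linking probability `p` in (0, 1).
#' @export
tune_p_in_ei <- function(truth, target_fold, background_per_mb = NULL,
                         length_bp = NULL) {
  fs <- truth$spec$features
  if (!is.null(background_per_mb)) fs$background_per_mb <- background_per_mb
  if (!is.null(length_bp)) fs$length_bp <- length_bp
  L <- as.numeric(GenomicRanges::width(truth$eis))
  if (length(L) == 0L) stopf("truth has no planted islands")
  gsize <- layout_size(truth$layout)
  d <- fs$background_per_mb / 1e6
  fold_of <- function(p) {
    d_eff <- d + p * length(L) / gsize
    m <- mean(1 - exp(-d_eff * (L + fs$length_bp)))
    m_bg <- mean(1 - exp(-d * (L + fs$length_bp)))
    (p + (1 - p) * m_bg) / m
  }
  stats::uniroot(function(p) fold_of(p) - target_fold,
                 lower = 1e-6, upper = 1 - 1e-6)$root
}

#' Simulate a feature set with designed island enrichment
#'
#' Each planted (margin-respecting) island independently receives one
#' feature interval centered inside it with probability `p_in_ei`;
#' background features are placed uniformly over the genome at
#' `background_per_mb` per Mb.  The expected observed overlap and expected
#' null mean are computable in closed form from the spec and are attached:
#' for an island of length L and feature length f, a Poisson background of
#' density d per bp hits it with probability `1 - exp(-d (L + f))`.
#'
#' @param truth a `sim_truth`.
#' @param p_in_ei,background_per_mb,length_bp overrides of
#'   `truth$spec$features`.
#' @param seed RNG seed.
#' @return A `GRanges` feature set; `attr(x, "expected")` holds
#'   `null_mean`, `observed`, `fold` under the closed-form model.
#' @export
simulate_features <- function(truth, p_in_ei = NULL, background_per_mb = NULL,
                              length_bp = NULL, seed = NULL) {
  stopifnot(inherits(truth, "sim_truth"))
  fs <- truth$spec$features
  if (!is.null(p_in_ei)) fs$p_in_ei <- p_in_ei
  if (!is.null(background_per_mb)) fs$background_per_mb <- background_per_mb
  if (!is.null(length_bp)) fs$length_bp <- length_bp
  with_seed(seed, {
    eis <- truth$eis
    linked <- GenomicRanges::GRanges(seqinfo = truth$layout)
    if (length(eis)) {
      take <- stats::runif(length(eis)) < fs$p_in_ei
      if (any(take)) {
        linked <- GenomicRanges::resize(
          GenomicRanges::granges(eis[take]), width = fs$length_bp,
          fix = "center")
      }
    }
    gsize <- layout_size(truth$layout)
    nbg <- stats::rpois(1, fs$background_per_mb * gsize / 1e6)
    bg <- GenomicRanges::GRanges(seqinfo = truth$layout)
    if (nbg > 0) {
      lens <- GenomeInfoDb::seqlengths(truth$layout)
      ch <- sample(GenomeInfoDb::seqnames(truth$layout), nbg, replace = TRUE,
                   prob = lens)
      s <- floor(stats::runif(nbg, 1, lens[ch] - fs$length_bp))
      bg <- GenomicRanges::GRanges(ch, IRanges::IRanges(
        start = s, width = fs$length_bp), seqinfo = truth$layout)
    }
    feats <- GenomicRanges::sort(c(linked, bg), ignore.strand = TRUE)
    d <- fs$background_per_mb / 1e6
    L <- as.numeric(GenomicRanges::width(eis))
    # the null must see the island-linked features too: a random placement
    # can land on them, so the effective density adds p_in_ei features per
    # island over the genome
    d_eff <- d + fs$p_in_ei * length(L) / gsize
    null_mean <- if (length(L)) mean(1 - exp(-d_eff * (L + fs$length_bp))) else NA_real_
    bg_rate <- if (length(L)) mean(1 - exp(-d * (L + fs$length_bp))) else NA_real_
    observed <- fs$p_in_ei + (1 - fs$p_in_ei) * bg_rate
    attr(feats, "expected") <- list(
      null_mean = null_mean, observed = observed,
      fold = observed / null_mean)
    S4Vectors::metadata(feats)$name <- "simulated features"
    feats
  })
}
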
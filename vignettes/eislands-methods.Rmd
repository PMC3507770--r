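---
title: "Methods: LOCK segmentation, euchromatin-island detection, and permutation enrichment"
author: "eislands"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: LOCK segmentation, euchromatin-island detection, and permutation enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eislands)
library(GenomicRanges)
```

## The problem

Dimethylation of histone H3 lysine 9 (H3K9me2) organizes into very large
domains — LOCKs (large organized chromatin K9-modifications), hundreds of kb
to Mb in scale — that expand as pluripotent cells differentiate, covering
roughly 40% of the genome in differentiated cell types at a 90th-quantile
cutoff. Inside these repressive bodies sit small (~1–10 kb) windows of very
low H3K9me2 signal. These euchromatin islands (EIs) are open-chromatin
pockets: they preferentially coincide with CTCF binding regions, DNase I
hypersensitive sites, transcription start sites and CpG islands, which makes
their reliable detection, and honest statistics for those coincidences, the
analytical core of the problem.

The measurements are ChIP-chip log2(ChIP/Input) ratios on whole-genome
tiling arrays with ~200 bp median probe spacing. `eislands` implements the
full path from probe-level tracks to enrichment tables:

1. **partial quantile normalization** of log-ratio tracks across arrays,
2. **LOCK segmentation** at a genome-wide quantile cutoff,
3. **EI detection** inside LOCK bodies by smoothing, bottom-percentile
   thresholding and filtering,
4. **length-matched permutation enrichment** of EI/feature overlap with
   Bonferroni correction, and
5. a **synthetic-data generator** that plants all of the above with ground
   truth, so every stage is testable without any external download.

## Signal model and normalization

Log ratios are treated as approximately symmetric about a background level,
with domain-scale additive elevation inside LOCKs. Normalization maps the
lower `lower_fraction` (default 0.75) of each track's empirical distribution
onto a common reference quantile curve (the pointwise mean of the tracks'
quantile functions, or a designated track). Values above the boundary
quantile are shifted by a constant so the transform is continuous and
strictly monotone. The rationale: the lower three quarters of probes are
non-enriched background whose distribution should agree across arrays, while
the enrichment tail carries the biology (differentiated cells have more
high-signal probes than pluripotent ones) and must not be flattened — which
is exactly what full quantile normalization would do.

Numerical conventions worth stating:

* quantile curves interpolate order statistics linearly at plotting
  positions $(r-1)/(n-1)$ (type-7 quantiles), so with equal-length tracks
  and `lower_fraction = 1` the procedure reproduces textbook quantile
  normalization exactly;
* the boundary is snapped to a realized plotting position, which makes the
  transform exactly idempotent against a fixed reference and keeps the
  shifted upper tail above the mapped lower part (no rank inversions);
* ties share an average rank and therefore remain ties.

## LOCK segmentation

`call_locks()` computes the cutoff $t$ as the genome-wide `quantile`
(default 0.90) of the probe values, takes maximal runs of consecutive
probes with value $\ge t$ (ties included, so an all-equal track becomes one
domain per chromosome — a documented degenerate case), merges runs separated
by at most `merge_gap_bp`, and keeps merged spans that satisfy the filters
below. Domain coordinates run from the first to the last probe of the span.

Parameter defaults and why:

* **`threshold_source = "raw"`.** Both the cutoff and the run statistic use
  raw probe values. A smoothed curve thresholded at its own (or the raw)
  90th percentile can never cover ~40% of the genome: with 40% of probes in
  domains, the pooled 90th percentile sits *inside* the domain mode, about
  0.7 SD above the domain mean, and a smoothed curve essentially never
  exceeds it. Raw-value runs with merging recover domain bodies because
  inside a shifted domain a quarter of the probes exceed the cutoff at ~800
  bp spacing, while outside they are ~15 kb apart. A smoothed mode is
  available and recorded in provenance.
* **`merge_gap_bp = 15000`.** The merge gap must exceed the span of an
  euchromatin island plus its flanking sub-threshold probes; otherwise a
  deep island splits its parent LOCK at calling time and is subsequently
  lost to the boundary-margin rule. 15 kb is comfortably above the ~8 kb
  island scale and far below the distance between separate domains.
* **`min_length_bp = 100000`.** LOCKs are 10^2–10^3 kb objects; 100 kb is
  the lower edge of that scale. It also rejects chance chains: isolated
  above-cutoff noise probes occur at ~1.3% outside domains and can chain
  through the merge gap, but such chains rarely span 100 kb.
* **`edge_min_probes = 2`.** A domain boundary must be anchored by at least
  two consecutive above-cutoff probes. A single noise probe within the
  merge gap of a true edge would otherwise drag the boundary outward into
  background, polluting the island threshold pool downstream.
* **`min_enrichment = 1.5`.** A called domain must contain above-cutoff
  probes at $\ge 1.5\times$ the genome-wide rate $1-q$. On a structureless
  track every probe set sits exactly at the background rate, so this filter
  is what guarantees zero calls on pure noise while leaving genuine domains
  (rates $\ge 2\times$ background in practice) untouched.

Raising the cutoff quantile never increases covered bp (tested property),
and the computed threshold is recorded in the output's metadata and in the
pipeline provenance, since it is the pivotal intermediate quantity.

## Euchromatin-island detection

`detect_eis()` follows a fixed order of operations:

1. restrict to probes inside called LOCKs;
2. smooth per LOCK with a 5,000 bp window (short, to keep small-region
   signal variation) — the window is truncated at LOCK edges and never
   crosses them, so outside values cannot leak in;
3. threshold $t$ = the 1st percentile (`low_percentile = 0.01`) of the
   smoothed values, pooled over in-LOCK probes by default;
4. candidate runs = maximal stretches of consecutive probes strictly below
   $t$ (strict, so constant regions yield nothing);
5. merge runs less than 1,000 bp apart;
6. drop merged runs shorter than 1,000 bp or with fewer than 10 probes;
7. drop runs whose edge lies within 20,000 bp of the parent LOCK's edge,
   measured edge-to-edge — log ratios decay at LOCK boundaries, and the
   margin prevents mistaking that decay for islands.

Merging precedes the length/probe filters so a dip fragmented by one noisy
probe is not spuriously discarded, and the boundary filter runs last so it
judges final island edges. Lengths and gaps are genomic spans (probe spans),
not probe counts. The percentile universe is configurable to "all probes"
(genome-wide smoothed values); the default follows the within-LOCK reading
since the threshold sentence directly follows the in-LOCK smoothing step.

### Operating regimes of the bottom-percentile rule

The 1% rule makes the threshold *relative*: it adapts to however much
low-signal territory exists inside LOCKs. Two regimes matter for
interpreting results (and the synthetic benchmarks):

* **Sparse islands** (island bp well below 1% of LOCK bp): the threshold
  rises into the noise floor. All true islands are caught, but smoothed
  noise excursions can sneak past the 10-probe/1-kb filters, costing
  precision.
* **Dense islands** (island bp well above 1%): the threshold sinks into the
  island mode and only the deepest cores survive, costing sensitivity for
  short islands.

The window between the regimes — island bp near 1% of LOCK bp — is where
the definition can represent the truth, and it is where the default
synthetic conditions sit. Because the planted island count is Poisson,
individual simulation seeds can still land outside the window; recovery
metrics reported by the acceptance script are therefore honest measurements
that fluctuate with the seed, not guarantees.

## Permutation enrichment

The observed statistic is either the fraction of islands sharing $\ge 1$ bp
with any feature (interval overlap; the table statistic) or the fraction of
query bp covered by merged features (base overlap; the domain-vs-PMD
statistic). The null draws `n_permutations` (default 1,000) random interval
sets whose number and lengths match the query exactly — multiset equality,
enforced in every draw — placed uniformly inside a universe: the
probe-covered genome (islands can only exist where probes exist, so the
null shares that support), the LOCK set, or any explicit segment set.
Segments are chosen with probability proportional to their number of valid
start positions for each length; null intervals are pairwise disjoint by
default (as island sets are), with a rejection cap that suggests allowing
overlap when the universe is too congested.

Fold enrichment is observed / null mean, with $0/0$ reported as 1 and
positive/0 as infinity. The empirical p-value uses the add-one rule
$p = (1 + \#\{null \ge obs\})/(n+1)$, upper-tailed, so $p$ is never zero
and the minimum reportable value at $n = 1000$ is $1/1001$ — matching the
"$<10^{-3}$" reporting convention. Families of feature tests are corrected
with Bonferroni ($p_{bonf} = \min(1, p \cdot k)$). Given a seed the whole
test is bit-reproducible, and the caller's RNG state is left untouched.

One calibration subtlety: the interval-overlap fraction of a small query
set is coarsely discrete, and ties between null draws and the observed
value make the add-one estimator conservative. Calibration checks therefore
use the effectively continuous base-overlap statistic, and the query must be
drawn from the same uniform-disjoint placement law as the null — a query
built by merging overlapping uniform intervals has a subtly different joint
law and shows as miscalibration even when the machinery is exact.

## The synthetic generator

`simulate_truth()` / `simulate_signal()` emulate a 2.1M-style tiling array:
a probe grid at 200 bp spacing (50 bp probes, ±25 bp uniform jitter to
avoid aliasing with the smoothing windows), Gaussian background
log-ratios, rectangular mean shifts of +1.5 SD inside planted LOCKs, and
rectangular dips of −2.5 SD for planted islands. The default study
conditions are two 10 Mb chromosomes, 40% LOCK coverage (the final domain
is trimmed so planted coverage is exact), Poisson(3) islands per LOCK of
3–8 kb placed at least 20 kb from LOCK edges, and log-normal LOCK lengths
with a 2 Mb median (`sdlog` 0.35). The 2 Mb median is a deliberate design
choice: with 3 islands per LOCK it puts planted island bp near 1% of LOCK
bp, the regime in which the bottom-percentile definition can represent all
of the planted truth (see above). `n_margin_dips` plants additional dips
*inside* the 20 kb margin to verify they are never reported.

Structure (grid, LOCKs, dips) and noise are seeded separately, so several
noise realizations of one truth support replicate-concordance experiments.
`simulate_features()` links one centered feature to each planted island
with probability `p_in_ei` on top of a uniform Poisson background, and
carries closed-form expectations: an island of length $L$ is hit by
background density $d$ with probability $1-e^{-d(L+f)}$, and the null mean
uses the effective density including the linked features a random placement
can land on. `tune_p_in_ei()` inverts the model to hit a target fold.

What the generator does *not* emulate: dye bias, GC/probe-sequence effects,
spatial array artifacts, copy-number structure, boundary signal decay
(planted domains are rectangular, so the 20 kb margin's real-data
motivation is exercised only via deliberately planted margin dips), or
replicate correlation beyond shared truth. Passing the synthetic benchmarks
therefore demonstrates the algorithmic contract, not robustness to every
real-data pathology.

## Problem sizes and test design

The test suite and acceptance script run entirely on generated data: the
demonstration genome is 2 × 10 Mb (100,000 probes), oracle-equivalence
checks use 100+ randomized instances of ≤ 1 Mb against brute-force
reimplementations (quadratic windowed means, per-base masks, sequential run
enumeration) at 10⁻⁹ tolerance, calibration uses 200–500 independent
permutation tests at $n = 199$, and the designed-enrichment experiment uses
~170 planted islands with $n = 1000$ permutations. These sizes keep the
whole suite in minutes on one CPU while leaving each statistical band
(±20% on fold, [0.03, 0.07] on type-I error at 0.05) well-powered.

## Known limitations

* The original normalization procedure behind "partial quantile
  normalization" is specified here by contract (lower-tail alignment with a
  continuity shift); equivalence with the historical implementation cannot
  be asserted.
* LOCK-calling window, minimum length and merge gap are not stated in the
  source methods; the defaults here are design choices recorded in
  provenance, and the reported coverage figures cannot arbitrate them
  uniquely.
* The bottom-percentile island definition is relative by construction; on
  genomes whose true island load is far from 1% of LOCK bp, sensitivity or
  precision against planted truth degrades as described above.
* Whole-genome tests treat the probe-covered genome as the null support;
  assembly gaps, centromeres and repeat masking are not modelled.
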
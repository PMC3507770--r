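# run/merge machinery shared by the LOCK and EI callers

# maximal runs of consecutive flagged probes within each group (chromosome,
# or parent domain).  Returns a data.frame with one row per run: group id and
# first/last probe index (into the original vectors).
flag_runs <- function(group, flag) {
  n <- length(flag)
  if (n == 0L || !any(flag)) {
    return(data.frame(group = integer(0), first = integer(0), last = integer(0)))
  }
  brk <- c(TRUE, group[-1] != group[-n] | flag[-1] != flag[-n])
  run_id <- cumsum(brk)
  keep <- flag
  first <- tapply(seq_len(n)[keep], run_id[keep], min)
  last <- tapply(seq_len(n)[keep], run_id[keep], max)
  data.frame(group = group[as.integer(first)],
             first = as.integer(first), last = as.integer(last))
}

# drop leading/trailing component runs of a merged group that have fewer
# than edge_min probes: a domain boundary defined by an isolated
# above-threshold probe is within noise, so edges must be anchored by a run
# of at least edge_min consecutive flagged probes.  Interior short runs are
# kept (they are bridged by the merge rule, not boundary-defining).
trim_edge_runs <- function(runs, edge_min) {
  if (edge_min <= 1L || nrow(runs) == 0L) return(runs)
  np <- runs$last - runs$first + 1L
  keep <- rep(TRUE, nrow(runs))
  for (id in unique(runs$merge_id)) {
    i <- which(runs$merge_id == id)
    while (length(i) && np[i[1]] < edge_min) { keep[i[1]] <- FALSE; i <- i[-1] }
    while (length(i) && np[i[length(i)]] < edge_min) {
      keep[i[length(i)]] <- FALSE; i <- i[-length(i)]
    }
  }
  runs[keep, , drop = FALSE]
}

# merge consecutive runs in the same group whose genomic gap passes the rule:
# gap <= gap_bp (strict = FALSE) or gap < gap_bp (strict = TRUE).
# run_start/run_end are 1-based closed genomic coordinates of each run; the
# gap between runs is start[i+1] - end[i] - 1 bp.
merge_runs <- function(runs, run_start, run_end, gap_bp, strict = FALSE) {
  k <- nrow(runs)
  if (k <= 1L) {
    runs$merge_id <- seq_len(k)
    return(runs)
  }
  gap <- run_start[-1] - run_end[-k] - 1
  same <- runs$group[-1] == runs$group[-k]
  join <- if (strict) same & gap < gap_bp else same & gap <= gap_bp
  runs$merge_id <- cumsum(c(TRUE, !join))
  runs
}
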
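# Shared fixtures, built in code.

# Minimal probe annotation: chromosomes tiled contiguously at `spacing` bp.
make_annotation <- function(n_chrom = 1L, probes_per_chrom = 100L,
                            spacing = 1e5) {
  do.call(rbind, lapply(seq_len(n_chrom), function(c) {
    k <- seq_len(probes_per_chrom)
    data.frame(chromosome = paste0("chr", c),
               start = (k - 1) * spacing, end = k * spacing,
               probe_id = sprintf("chr%d_P%05d", c, k),
               stringsAsFactors = FALSE)
  }))
}

# Integer copies -> call states used by the simulator truth.
truth_calls <- function(copies) {
  ifelse(copies < 2, -1L, ifelse(copies == 2, 0L,
                                 ifelse(copies == 3, 1L, 2L)))
}

# Independent brute-force maximal arc statistic (oracle for the CBS scan):
# plain double loop over all arcs with the pooled-variance t statistic.
brute_max_arc <- function(x, min_width = 2L) {
  n <- length(x)
  best <- -Inf; bi <- NA; bj <- NA
  for (i in 0:(n - min_width)) {
    for (j in (i + min_width):min(n, i + n - min_width)) {
      inside <- x[(i + 1):j]
      outside <- x[-((i + 1):j)]
      k <- length(inside); m <- length(outside)
      ssq <- sum((inside - mean(inside))^2) + sum((outside - mean(outside))^2)
      mse <- if (n > 2) ssq / (n - 2) else 0
      s <- if (mse <= 1e-14 * max(1, mean(x^2))) {
        if (abs(mean(inside) - mean(outside)) <= 1e-12) 0 else Inf
      } else {
        abs(mean(inside) - mean(outside)) / sqrt(mse * (1 / k + 1 / m))
      }
      if (s > best) { best <- s; bi <- i; bj <- j }
    }
  }
  list(stat = best, i = bi, j = bj)
}

# Hand-computed two-group log-rank O/E/V aggregation (oracle).
brute_logrank <- function(times, events, group) {
  group <- as.numeric(group)
  et <- sort(unique(times[events == 1]))
  U <- 0; V <- 0
  for (t in et) {
    at_risk <- times >= t
    n <- sum(at_risk); n1 <- sum(at_risk & group == 1)
    d <- sum(times == t & events == 1)
    d1 <- sum(times == t & events == 1 & group == 1)
    U <- U + d1 - d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  if (V > 0) U^2 / V else 0
}

# Exact permutation p over all distinct binary labelings with the observed
# carrier count (n <= 10 or so).
exact_perm_p <- function(times, events, group) {
  n <- length(times)
  k <- sum(group)
  obs <- brute_logrank(times, events, group)
  sets <- utils::combn(n, k)
  stats <- apply(sets, 2, function(idx) {
    g <- rep(0, n); g[idx] <- 1
    brute_logrank(times, events, g)
  })
  mean(stats >= obs - 1e-12)
}

# Kruskal-Wallis H from first principles (midranks + tie correction).
brute_kw <- function(values, groups) {
  groups <- factor(groups)
  N <- length(values)
  r <- rank(values)
  H <- 12 / (N * (N + 1)) *
    sum(tapply(r, groups, function(z) length(z) * (mean(z) - (N + 1) / 2)^2))
  ties <- table(values)
  corr <- 1 - sum(ties^3 - ties) / (N^3 - N)
  H / corr
}
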
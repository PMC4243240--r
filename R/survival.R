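#' Cohort eligibility filter for supervised analysis
#'
#' Keeps samples that received at least three treatment cycles, or two
#' cycles if the patient died of (rapidly) progressive disease, and are not
#' microsatellite instable. Samples with missing cycle counts are excluded
#' and reported.
#'
#' @param clinical Clinical data.frame with columns `sample_id`, `cycles`,
#'   `death_progression`, `msi`.
#' @return Data.frame with `sample_id`, `eligible`, `reason` (empty string
#'   when eligible).
#' @export
filter_cohort <- function(clinical) {
  req <- c("sample_id", "cycles", "death_progression", "msi")
  miss <- setdiff(req, names(clinical))
  if (length(miss)) stop("clinical table lacks columns: ",
                         paste(miss, collapse = ", "))
  cyc <- clinical$cycles
  na_cyc <- is.na(cyc)
  enough <- !na_cyc & (cyc >= 3 | (cyc >= 2 & clinical$death_progression))
  eligible <- enough & !clinical$msi
  reason <- character(nrow(clinical))
  reason[na_cyc] <- "missing cycles"
  reason[!na_cyc & !enough] <- "insufficient cycles"
  reason[clinical$msi & reason == ""] <- "MSI"
  if (any(na_cyc))
    message("filter_cohort: ", sum(na_cyc),
            " sample(s) with missing cycle count excluded")
  data.frame(sample_id = clinical$sample_id, eligible = eligible,
             reason = reason, stringsAsFactors = FALSE)
}

#' Kaplan-Meier estimate with median and confidence interval
#'
#' Product-limit estimator; the median is the smallest time at which the
#' survival estimate drops to 0.5 or below, with confidence limits from the
#' Greenwood variance on the log(-log S) scale. When the curve never reaches
#' 0.5 the median is `NA`.
#'
#' @param times Non-negative follow-up times.
#' @param events Event indicators (1 progression/death, 0 censored).
#' @param conf_level Confidence level for the interval.
#' @return List with the step-curve coordinates (`time`, `surv`, `lower`,
#'   `upper`), `median`, `median_lower`, `median_upper`, `n`, `n_events`.
#' @export
km_estimate <- function(times, events, conf_level = 0.95) {
  stopifnot(length(times) == length(events), length(times) >= 1)
  fit <- survival::survfit(survival::Surv(times, events) ~ 1,
                           conf.type = "log-log", conf.int = conf_level)
  tab <- summary(fit)$table
  list(time = fit$time, surv = fit$surv,
       lower = fit$lower, upper = fit$upper,
       median = unname(tab["median"]),
       median_lower = unname(tab[grep("LCL", names(tab))]),
       median_upper = unname(tab[grep("UCL", names(tab))]),
       n = length(times), n_events = sum(events))
}

# Internal: precompute risk-set and event indicator matrices over distinct
# event times, enabling vectorised log-rank statistics over many label
# vectors at once. Censored observations tied with events stay in the risk
# set at that time (censored-after-events convention).
logrank_prep <- function(times, events) {
  et <- sort(unique(times[events == 1]))
  K <- length(et)
  n <- length(times)
  if (K == 0)
    return(list(K = 0L, n = n))
  R <- outer(et, times, function(t, s) as.numeric(s >= t))  # K x n at-risk
  D <- outer(et, times, "==") * rep(events, each = K)        # K x n events
  d <- rowSums(D)
  nr <- rowSums(R)
  list(K = K, n = n, R = R, D = D, d = d, nr = nr)
}

# Internal: log-rank U, V and chi-square statistic for label matrix G
# (n x B of 0/1 group indicators). Returns list(U, V, stat) of length B.
logrank_stat_many <- function(prep, G) {
  if (prep$K == 0L) {
    B <- ncol(G)
    return(list(U = numeric(B), V = numeric(B), stat = numeric(B)))
  }
  N1 <- prep$R %*% G          # K x B at-risk in group 1
  D1 <- prep$D %*% G          # K x B events in group 1
  d <- prep$d; nr <- prep$nr
  U <- colSums(D1 - d * N1 / nr)
  vfac <- ifelse(nr > 1, d * (nr - d) / (nr - 1), 0)
  V <- colSums(vfac * (N1 / nr) * (1 - N1 / nr))
  stat <- ifelse(V > 0, U^2 / V, 0)
  list(U = U, V = V, stat = stat)
}

#' Two-group log-rank statistic
#'
#' The standard chi-square-form log-rank statistic: `U = sum(O1 - E1)` over
#' distinct event times, `V` the sum of hypergeometric variances, statistic
#' `U^2 / V` (0 when there are no events or V = 0).
#'
#' @param times Follow-up times.
#' @param events Event indicators (1/0).
#' @param group Logical or 0/1 group membership.
#' @return List with `U`, `V`, `stat` and the asymptotic chi-square(1)
#'   `p_asymptotic`.
#' @export
logrank_statistic <- function(times, events, group) {
  group <- as.numeric(group)
  if (length(unique(group)) < 2)
    stop("both groups must be non-empty")
  prep <- logrank_prep(times, events)
  r <- logrank_stat_many(prep, matrix(group, ncol = 1))
  list(U = r$U[1], V = r$V[1], stat = r$stat[1],
       p_asymptotic = pchisq(r$stat[1], df = 1, lower.tail = FALSE))
}

#' Permutation p-value for the log-rank statistic
#'
#' Permutes carrier labels over the samples `B` times and reports
#' `p = (1 + #(permuted stat >= observed)) / (B + 1)`, so p is never 0 and
#' never below `1/(B+1)`. Degenerate labels (all identical) give p = 1.
#'
#' @param times,events Survival data.
#' @param group Carrier labels (logical or 0/1).
#' @param B Number of permutations (default 10000).
#' @param seed Integer seed; the result is deterministic given it and
#'   invariant to sample order.
#' @return List with `p`, `stat` (observed) and `perm_stats`.
#' @export
permutation_pvalue <- function(times, events, group, B = 10000L, seed = 1L) {
  if (B < 1) stop("B must be >= 1")
  group <- as.numeric(group)
  if (length(unique(group)) < 2)
    return(list(p = 1, stat = 0, perm_stats = numeric(0)))
  # canonical sample order so that the p-value is order-invariant
  ord <- order(times, events, group)
  times <- times[ord]; events <- events[ord]; group <- group[ord]
  prep <- logrank_prep(times, events)
  obs <- logrank_stat_many(prep, matrix(group, ncol = 1))$stat[1]
  n <- length(group)
  G <- with_seed(seed, {
    m <- matrix(0, n, B)
    for (b in seq_len(B)) m[, b] <- group[sample.int(n)]
    m
  })
  perm <- logrank_stat_many(prep, G)$stat
  # count ties up to floating-point noise (complementary labelings give
  # mathematically equal statistics that may differ in the last bit)
  list(p = (1 + sum(perm >= obs - 1e-9)) / (B + 1), stat = obs,
       perm_stats = perm)
}

#' Genome-wide permutation log-rank association per treatment arm
#'
#' For every region and aberration type (gain: call >= 1; loss: call <= -1)
#' with at least `min_group` carriers and `min_group` non-carriers within an
#' arm's eligible samples, computes the two-group log-rank statistic of
#' progression-free survival and its permutation p-value. All regions of an
#' arm share one permutation stream, and the permuted statistics are kept so
#' that permutation-based FDRs can be computed afterwards
#' ([permutation_fdr()]).
#'
#' Two significance tiers are flagged after all arms have run: `tier1`,
#' p < `alpha_tier1` in the arm at hand; `tier2`, p < `alpha_tier2` in at
#' least two arms for the same region and type.
#'
#' @param status Region x sample integer call matrix (consensus calls from
#'   [reduce_to_subregions()]); column names are sample ids.
#' @param clinical Clinical table (`sample_id`, `arm`, `pfs_days`, `event`,
#'   `cycles`, `death_progression`, `msi`).
#' @param B Permutations per arm (default 10000).
#' @param seed Integer base seed (per-arm streams are derived from it).
#' @param min_group Minimum carriers and non-carriers per test.
#' @param alpha_tier1,alpha_tier2 Tier thresholds (defaults 0.005 / 0.05).
#' @param types Aberration types to test.
#' @param apply_filter Apply [filter_cohort()] before testing (default TRUE).
#' @return An object of class `cna_assoc`: `results` data.frame (region_id,
#'   arm, type, n_carrier, n_noncarrier, stat, p, median_carrier,
#'   median_noncarrier, tier1, tier2, skipped reason), `archive` of permuted
#'   statistics per arm, and the call parameters.
#' @export
associate_genomewide <- function(status, clinical, B = 10000L, seed = 1L,
                                 min_group = 5L,
                                 alpha_tier1 = 0.005, alpha_tier2 = 0.05,
                                 types = c("gain", "loss"),
                                 apply_filter = TRUE) {
  stopifnot(is.matrix(status), !is.null(colnames(status)))
  if (apply_filter) {
    elig <- filter_cohort(clinical)
    keep <- elig$sample_id[elig$eligible]
    clinical <- clinical[clinical$sample_id %in% keep, , drop = FALSE]
  }
  clinical <- clinical[clinical$sample_id %in% colnames(status), , drop = FALSE]
  arms <- unique(clinical$arm)
  region_ids <- rownames(status)
  if (is.null(region_ids)) region_ids <- sprintf("R%04d", seq_len(nrow(status)))
  res <- list()
  archive <- list()
  for (ai in seq_along(arms)) {
    a <- arms[ai]
    cl <- clinical[clinical$arm == a, , drop = FALSE]
    # canonical order: permutation results do not depend on input order
    cl <- cl[order(cl$pfs_days, cl$event, cl$sample_id), , drop = FALSE]
    n <- nrow(cl)
    sm <- status[, cl$sample_id, drop = FALSE]
    prep <- logrank_prep(cl$pfs_days, cl$event)
    perm_idx <- with_seed(child_seed(seed, ai), {
      m <- matrix(0L, n, B)
      for (b in seq_len(B)) m[, b] <- sample.int(n)
      m
    })
    arm_archive <- list()
    for (type in types) {
      carrier <- t(apply(sm, 1, region_carrier_status, type = type))
      for (r in seq_len(nrow(sm))) {
        g <- as.numeric(carrier[r, ])
        nc <- sum(g)
        nn <- n - nc
        if (nc < min_group || nn < min_group) {
          res[[length(res) + 1L]] <- data.frame(
            region_id = region_ids[r], arm = a, type = type,
            n_carrier = nc, n_noncarrier = nn, stat = NA_real_, p = NA_real_,
            median_carrier = NA_real_, median_noncarrier = NA_real_,
            skipped = "group below min_group", stringsAsFactors = FALSE)
          next
        }
        obs <- logrank_stat_many(prep, matrix(g, ncol = 1))$stat[1]
        G <- matrix(g[perm_idx], n, B)
        perm <- logrank_stat_many(prep, G)$stat
        p <- (1 + sum(perm >= obs - 1e-9)) / (B + 1)
        med_c <- km_estimate(cl$pfs_days[g == 1], cl$event[g == 1])$median
        med_n <- km_estimate(cl$pfs_days[g == 0], cl$event[g == 0])$median
        arm_archive[[paste(region_ids[r], type, sep = ".")]] <- perm
        res[[length(res) + 1L]] <- data.frame(
          region_id = region_ids[r], arm = a, type = type,
          n_carrier = nc, n_noncarrier = nn, stat = obs, p = p,
          median_carrier = med_c, median_noncarrier = med_n,
          skipped = "", stringsAsFactors = FALSE)
      }
    }
    archive[[a]] <- list(B = B,
                         perm_stats = do.call(rbind, arm_archive))
  }
  results <- do.call(rbind, res)
  results$tier1 <- !is.na(results$p) & results$p < alpha_tier1
  # tier 2: p < alpha_tier2 in >= 2 arms for the same region and type
  key <- paste(results$region_id, results$type)
  hit <- !is.na(results$p) & results$p < alpha_tier2
  n_arms_hit <- tapply(hit, key, sum)
  results$tier2 <- hit & n_arms_hit[key] >= 2
  results <- results[order(is.na(results$p), results$p), , drop = FALSE]
  rownames(results) <- NULL
  structure(list(results = results, archive = archive, B = B, seed = seed,
                 min_group = min_group, alpha_tier1 = alpha_tier1,
                 alpha_tier2 = alpha_tier2, arms = arms),
            class = "cna_assoc")
}

#' @export
print.cna_assoc <- function(x, ...) {
  tested <- x$results[x$results$skipped == "", , drop = FALSE]
  cat("Genome-wide permutation log-rank association\n")
  cat(sprintf("Arms: %s; %d region x type tests (B = %d)\n",
              paste(x$arms, collapse = ", "), nrow(tested), x$B))
  cat(sprintf("Tier-1 hits (p < %.3g in an arm): %d; tier-2 (p < %.3g in >= 2 arms): %d\n",
              x$alpha_tier1, sum(tested$tier1), x$alpha_tier2,
              sum(tested$tier2)))
  invisible(x)
}

#' @export
summary.cna_assoc <- function(object, n = 10, ...) {
  print(object)
  tested <- object$results[object$results$skipped == "", , drop = FALSE]
  cat("\nTop associations:\n")
  print(utils::head(tested[, c("region_id", "arm", "type", "n_carrier",
                               "stat", "p", "median_carrier",
                               "median_noncarrier")], n), row.names = FALSE)
  invisible(object)
}

#' @export
plot.cna_assoc <- function(x, arm = NULL, ...) {
  tested <- x$results[x$results$skipped == "", , drop = FALSE]
  if (!is.null(arm)) tested <- tested[tested$arm == arm, , drop = FALSE]
  idx <- seq_len(nrow(tested))
  plot(idx, -log10(tested$p),
       pch = ifelse(tested$type == "gain", 24, 25),
       bg = ifelse(tested$tier1, "red", "grey"),
       xlab = "region x type (ordered by p)",
       ylab = expression(-log[10](p)),
       main = if (is.null(arm)) "Region-PFS associations" else
         paste("Region-PFS associations,", arm), ...)
  abline(h = -log10(x$alpha_tier1), lty = 2)
  invisible(x)
}

#' Permutation-based false discovery rate at a p-value threshold
#'
#' Using the permuted statistic archive of [associate_genomewide()], each
#' permutation replicate is converted to per-region permutation p-values,
#' and `FDR(t)` is the average number of permuted p-values at or below `t`
#' divided by the observed discovery count at `t` (reported as 1 when there
#' are no observed discoveries).
#'
#' @param assoc A `cna_assoc` object.
#' @param threshold P-value threshold `t`.
#' @param arm Optional arm to restrict to (default: pool all arms).
#' @return List with `fdr`, `n_observed`, `expected_false`.
#' @export
permutation_fdr <- function(assoc, threshold = 0.005, arm = NULL) {
  stopifnot(inherits(assoc, "cna_assoc"))
  arms <- if (is.null(arm)) assoc$arms else arm
  obs <- assoc$results
  obs <- obs[obs$skipped == "" & obs$arm %in% arms, , drop = FALSE]
  n_obs <- sum(obs$p <= threshold)
  counts <- NULL
  for (a in arms) {
    S <- assoc$archive[[a]]$perm_stats
    if (is.null(S) || nrow(S) == 0) next
    Bp <- ncol(S)
    # permutation p of replicate b within its own row's null distribution
    rk <- t(apply(S, 1, rank, ties.method = "min"))
    pmat <- (Bp - rk + 1) / (Bp + 1)
    cnt <- colSums(pmat <= threshold)
    counts <- if (is.null(counts)) cnt else counts + cnt
  }
  if (is.null(counts)) stop("no permutation archive available")
  expected_false <- mean(counts)
  fdr <- if (n_obs == 0) 1 else min(1, expected_false / n_obs)
  list(fdr = fdr, n_observed = n_obs, expected_false = expected_false)
}

#' Between-arm survival comparisons stratified by region status
#'
#' Within carriers, and separately within non-carriers, of a region
#' aberration, compares progression-free survival between every pair of
#' treatment arms with the asymptotic log-rank test and reports per-arm
#' Kaplan-Meier medians. Pairs with an empty stratum are reported `NA`.
#'
#' @param carrier Named logical vector of carrier flags (names = sample_id).
#' @param clinical Clinical table; only eligible samples should be passed.
#' @param arms Arms to compare (default: all present).
#' @param alpha Significance threshold recorded alongside (default 0.005).
#' @return Data.frame: `stratum`, `arm1`, `arm2`, `n1`, `n2`, `stat`, `p`,
#'   `significant`.
#' @export
between_arm_tests <- function(carrier, clinical, arms = NULL, alpha = 0.005) {
  if (is.null(arms)) arms <- unique(clinical$arm)
  if (length(arms) < 2) stop("need at least two arms")
  carrier <- carrier[clinical$sample_id]
  out <- list()
  for (stratum in c(TRUE, FALSE)) {
    cl <- clinical[which(carrier == stratum), , drop = FALSE]
    for (i in seq_len(length(arms) - 1)) for (j in (i + 1):length(arms)) {
      c1 <- cl[cl$arm == arms[i], , drop = FALSE]
      c2 <- cl[cl$arm == arms[j], , drop = FALSE]
      if (nrow(c1) == 0 || nrow(c2) == 0) {
        stat <- NA_real_; p <- NA_real_
      } else {
        lr <- logrank_statistic(c(c1$pfs_days, c2$pfs_days),
                                c(c1$event, c2$event),
                                rep(c(0, 1), c(nrow(c1), nrow(c2))))
        stat <- lr$stat; p <- lr$p_asymptotic
      }
      out[[length(out) + 1L]] <- data.frame(
        stratum = if (stratum) "carrier" else "noncarrier",
        arm1 = arms[i], arm2 = arms[j], n1 = nrow(c1), n2 = nrow(c2),
        stat = stat, p = p, significant = !is.na(p) & p < alpha,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
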
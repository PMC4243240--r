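test_that("cohort filtering applies the cycle and MSI rules", {
  cl <- data.frame(
    sample_id = paste0("s", 1:6),
    cycles = c(3L, 2L, 2L, 5L, NA, 1L),
    death_progression = c(FALSE, TRUE, FALSE, FALSE, FALSE, TRUE),
    msi = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE))
  expect_message(f <- filter_cohort(cl), "missing cycle")
  expect_equal(f$eligible, c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_equal(f$reason[4], "MSI")
  expect_error(filter_cohort(cl[, -3]), "lacks columns")
})

test_that("Kaplan-Meier estimates match the product-limit computation", {
  km <- km_estimate(c(10, 20, 30), c(1, 1, 1))
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0))
  expect_equal(km$median, 20)
  expect_equal(km_estimate(5, 1)$median, 5)
  expect_true(is.na(km_estimate(c(10, 20), c(0, 0))$median))
})

test_that("KM medians recover ln2/lambda for exponential data", {
  set.seed(41)
  t <- rexp(4000, log(2) / 300)
  expect_lt(abs(km_estimate(t, rep(1, 4000))$median - 300) / 300, 0.05)
})

test_that("the log-rank statistic matches the hand-computed O/E/V table", {
  lr <- logrank_statistic(c(1, 2, 3, 4), c(1, 1, 1, 1), c(1, 1, 0, 0))
  expect_equal(lr$U, 7 / 6, tolerance = 1e-9)
  expect_equal(lr$V, 17 / 36, tolerance = 1e-9)
  expect_equal(lr$stat, (7 / 6)^2 / (17 / 36), tolerance = 1e-9)
  # identical groups: statistic 0
  lr0 <- logrank_statistic(c(1, 1, 2, 2), c(1, 1, 1, 1), c(1, 0, 1, 0))
  expect_equal(lr0$stat, 0)
  # no events at all
  expect_equal(logrank_statistic(c(1, 2), c(0, 0), c(1, 0))$stat, 0)
})

test_that("the log-rank statistic agrees with survdiff and the oracle", {
  set.seed(43)
  for (rep in 1:5) {
    n <- 40
    t <- rexp(n, 0.01); e <- rbinom(n, 1, 0.8); g <- rbinom(n, 1, 0.5)
    if (length(unique(g)) < 2) next
    got <- logrank_statistic(t, e, g)$stat
    expect_equal(got, brute_logrank(t, e, g), tolerance = 1e-9)
    sd_ <- survival::survdiff(survival::Surv(t, e) ~ g)
    expect_equal(got, unname(sd_$chisq), tolerance = 1e-6)
  }
})

test_that("permutation p-values follow the plus-one convention and enumeration", {
  # strongly separated groups, unbalanced so that no random permutation can
  # tie the observed statistic: observed beats every permutation
  t <- c(1:20, 1001:1040); e <- rep(1, 60); g <- rep(c(1, 0), c(20, 40))
  pp <- permutation_pvalue(t, e, g, B = 999, seed = 1)
  expect_equal(pp$p, 1 / 1000)
  # n <= 8: permutation p matches exhaustive enumeration
  set.seed(44)
  for (rep in 1:3) {
    t <- round(rexp(8, 0.1), 2); e <- rbinom(8, 1, 0.9)
    g <- rep(c(1, 0), each = 4)
    p_exact <- exact_perm_p(t, e, g)
    p_mc <- permutation_pvalue(t, e, g, B = 4000, seed = rep)$p
    expect_lt(abs(p_mc - p_exact), 0.03)
  }
  # degenerate labels
  expect_equal(permutation_pvalue(1:4, rep(1, 4), rep(1, 4), B = 10)$p, 1)
})

test_that("permutation p is deterministic and invariant to sample order", {
  set.seed(45)
  t <- rexp(30, 0.01); e <- rbinom(30, 1, 0.8); g <- rbinom(30, 1, 0.4)
  p1 <- permutation_pvalue(t, e, g, B = 500, seed = 9)$p
  p2 <- permutation_pvalue(t, e, g, B = 500, seed = 9)$p
  ord <- sample(30)
  p3 <- permutation_pvalue(t[ord], e[ord], g[ord], B = 500, seed = 9)$p
  expect_identical(p1, p2)
  expect_identical(p1, p3)
})

test_that("genome-wide association flags a planted driver and skips small groups", {
  drv <- driver_spec("chr1", 0, 3e6, "loss", carrier_fraction = 0.3,
                     hazard_ratio_per_arm = c(A = 3))
  cc <- cohort_config(arms = c("A", "B"), n_samples_per_arm = c(80, 80),
                      n_chromosomes = 2, probes_per_chromosome = 40,
                      probe_spacing = 2e5, background_aberration_rate = 2,
                      msi_fraction = 0, driver_regions = list(drv), seed = 8)
  co <- simulate_cohort(cc)
  calls <- truth_calls(co$truth$copies)
  sub <- reduce_to_subregions(calls, co$annotation, tolerance = 0)
  assoc <- associate_genomewide(sub$consensus, co$clinical, B = 500,
                                seed = 2, min_group = 5)
  res <- assoc$results
  # the driver interval regions should be the top loss hits in arm A
  drv_regions <- sub$regions$region_id[sub$regions$chromosome == "chr1" &
                                         sub$regions$start < 3e6]
  hitA <- res[res$arm == "A" & res$type == "loss" &
                res$region_id %in% drv_regions, ]
  expect_true(any(hitA$p < 0.01, na.rm = TRUE))
  # skipped records carry a reason
  sk <- res[res$skipped != "", ]
  if (nrow(sk)) expect_true(all(is.na(sk$p)))
  # medians are reported for tested rows
  ok <- res[res$skipped == "", ]
  expect_true(all(is.finite(ok$stat)))
})

test_that("permutation FDR is near 1 under the null and small under signal", {
  set.seed(46)
  n <- 60
  cl <- data.frame(sample_id = sprintf("s%02d", 1:n), arm = "A",
                   pfs_days = rexp(n, 0.01), event = rbinom(n, 1, 0.8),
                   cycles = 5L, death_progression = FALSE, msi = FALSE)
  status <- matrix(sample(c(0L, 1L), 40 * n, replace = TRUE), 40, n,
                   dimnames = list(sprintf("R%02d", 1:40), cl$sample_id))
  assoc <- associate_genomewide(status, cl, B = 400, seed = 3,
                                types = "gain")
  f <- permutation_fdr(assoc, threshold = 0.05)
  if (f$n_observed > 0) expect_gte(f$fdr, 0.3) else expect_equal(f$fdr, 1)
  # planted signal: carriers of half the regions progress much faster
  carrier <- rbinom(n, 1, 0.4)
  cl2 <- cl
  cl2$pfs_days <- rexp(n, ifelse(carrier == 1, 0.05, 0.01))
  status2 <- status
  status2[1:20, ] <- matrix(rep(carrier, 20), 20, byrow = TRUE)
  assoc2 <- associate_genomewide(status2, cl2, B = 400, seed = 3,
                                 types = "gain")
  f2 <- permutation_fdr(assoc2, threshold = 0.005)
  expect_lt(f2$fdr, 0.5)
})

test_that("between-arm tests stratify by carrier status", {
  set.seed(47)
  n <- 240
  arm <- rep(c("A", "B", "C"), each = n / 3)
  carrier <- rbinom(n, 1, 0.5) == 1
  # arm B has halved hazard among carriers only
  rate <- ifelse(arm == "B" & carrier, 0.005, 0.01)
  cl <- data.frame(sample_id = sprintf("s%03d", 1:n), arm = arm,
                   pfs_days = rexp(n, rate), event = 1L,
                   cycles = 5L, death_progression = FALSE, msi = FALSE)
  names(carrier) <- cl$sample_id
  bt <- between_arm_tests(carrier, cl, alpha = 0.005)
  expect_equal(nrow(bt), 6)  # 3 pairs x 2 strata
  ab_carrier <- bt$p[bt$stratum == "carrier" & bt$arm1 == "A" & bt$arm2 == "B"]
  ab_noncarr <- bt$p[bt$stratum == "noncarrier" & bt$arm1 == "A" &
                       bt$arm2 == "B"]
  expect_lt(ab_carrier, 0.005)
  expect_gt(ab_noncarr, 0.005)
  # empty stratum -> NA
  bt2 <- between_arm_tests(setNames(rep(TRUE, n), cl$sample_id), cl)
  expect_true(all(is.na(bt2$p[bt2$stratum == "noncarrier"])))
})

test_that("clustering separates silent from aberrant genomes", {
  set.seed(48)
  np <- 50
  silent <- matrix(0L, np, 40)
  # aberrant genomes share a recurrent aberration pattern with sample noise
  base <- sample(c(-1L, 0L, 1L), np, replace = TRUE, prob = c(0.3, 0.4, 0.3))
  aberrant <- sapply(1:60, function(s) {
    x <- base
    flip <- sample(np, 5)
    x[flip] <- sample(c(-1L, 0L, 1L), 5, replace = TRUE)
    x
  })
  calls <- cbind(silent, aberrant)
  colnames(calls) <- sprintf("s%03d", 1:100)
  clu <- cluster_samples(calls, k = 2)
  truth <- rep(1:2, c(40, 60))
  agree <- max(mean(clu$labels == truth), mean(clu$labels == 3 - truth))
  expect_gte(agree, 0.95)
  expect_error(cluster_samples(calls, k = 101), "exceeds")
})

test_that("cluster enrichment reproduces a chi-square association", {
  # silent-cluster MSI enrichment pattern: 19/21 MSI in the small cluster
  labels <- rep(c(1, 2), c(97, 252))
  flags <- c(rep(TRUE, 19), rep(FALSE, 78), rep(TRUE, 2), rep(FALSE, 250))
  enr <- cluster_enrichment(labels, flags)
  expect_lt(enr$p, 0.001)
  expect_equal(sum(enr$table), 349)
})
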
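test_that("probe annotation tiles chromosomes at the requested spacing", {
  cc <- cohort_config(n_chromosomes = 2, probes_per_chromosome = 100,
                      probe_spacing = 1e5)
  ann <- simulate_probe_annotation(cc)
  expect_equal(nrow(ann), 200)
  chr1 <- ann[ann$chromosome == "chr1", ]
  expect_equal(max(chr1$end), 1e7)
  expect_true(all(diff(chr1$start) == 1e5))
  expect_false(anyDuplicated(ann$probe_id) > 0)
  # ~17 kb spacing spans ~17 Mb over 1,000 probes
  cc2 <- cohort_config(n_chromosomes = 1, probes_per_chromosome = 1000,
                       probe_spacing = 17000)
  expect_equal(max(simulate_probe_annotation(cc2)$end), 17e6)
  # identical config -> identical annotation
  expect_identical(simulate_probe_annotation(cc), simulate_probe_annotation(cc))
  expect_error(cohort_config(probes_per_chromosome = 0), "positive")
})

test_that("noiseless undiluted profiles sit on exact copy-number levels", {
  cc <- cohort_config(arms = "A", n_samples_per_arm = 8, n_chromosomes = 2,
                      probes_per_chromosome = 50, noise_sd = 0,
                      wave_amplitude = 0, purity_range = c(1, 1),
                      background_aberration_rate = 4, msi_fraction = 0,
                      seed = 7)
  co <- simulate_cohort(cc)
  levels_ok <- co$ratios %in% c(log2(c(1, 3, 6) / 2), log2(2^-10), 0)
  expect_true(all(levels_ok))
  expect_identical(co$ratios, simulate_cohort(cc)$ratios)
})

test_that("the dilution law holds exactly at zero noise", {
  cc <- cohort_config(arms = "A", n_samples_per_arm = 6, n_chromosomes = 1,
                      probes_per_chromosome = 40, noise_sd = 0,
                      wave_amplitude = 0, purity_range = c(0.6, 0.9),
                      background_aberration_rate = 3, msi_fraction = 0,
                      seed = 11)
  co <- simulate_cohort(cc)
  p <- co$truth$purity
  expected <- log2(pmax(sweep(co$truth$copies / 2, 2, p, "*") +
                          rep(1 - p, each = nrow(co$ratios)), 2^-10))
  expect_equal(unname(co$ratios), unname(expected), tolerance = 1e-12)
})

test_that("driver carriers follow the binomial expectation", {
  drv <- driver_spec("chr1", 0, 2e6, "loss", carrier_fraction = 0.25,
                     hazard_ratio_per_arm = c(A = 2.5))
  cc <- cohort_config(arms = "A", n_samples_per_arm = 100, n_chromosomes = 1,
                      probes_per_chromosome = 50, probe_spacing = 1e5,
                      msi_fraction = 0, driver_regions = list(drv), seed = 3)
  co <- simulate_cohort(cc)
  k <- sum(co$truth$carriers[, 1])
  # 25 +/- 4 binomial sd (sd = sqrt(100 * .25 * .75) ~ 4.3)
  expect_gt(k, 25 - 4 * 4.33)
  expect_lt(k, 25 + 4 * 4.33)
  # carried loss visible in the truth copies over the driver interval
  rows <- which(co$annotation$chromosome == "chr1" &
                  co$annotation$start < 2e6)
  expect_true(all(co$truth$copies[rows, co$truth$carriers[, 1]] == 1L))
})

test_that("null drivers leave carrier and non-carrier survival alike", {
  drv <- driver_spec("chr1", 0, 2e6, "gain", carrier_fraction = 0.5,
                     hazard_ratio_per_arm = c(A = 1))
  cc <- cohort_config(arms = "A", n_samples_per_arm = 1000, n_chromosomes = 1,
                      probes_per_chromosome = 20, probe_spacing = 1e5,
                      censoring_rate = 0,
                      baseline_median_pfs = 200, msi_fraction = 0,
                      driver_regions = list(drv), seed = 5)
  co <- simulate_cohort(cc)
  carrier <- co$truth$carriers[, 1]
  m1 <- km_estimate(co$clinical$pfs_days[carrier],
                    co$clinical$event[carrier])$median
  m0 <- km_estimate(co$clinical$pfs_days[!carrier],
                    co$clinical$event[!carrier])$median
  # both near ln2/lambda = 200 days within Monte-Carlo error
  expect_lt(abs(m1 - m0) / 200, 0.15)
  expect_lt(abs(m1 - 200) / 200, 0.15)
})

test_that("censoring rate is tuned to its target", {
  cc <- cohort_config(arms = "A", n_samples_per_arm = 2000, n_chromosomes = 1,
                      probes_per_chromosome = 10, censoring_rate = 0.3,
                      msi_fraction = 0, background_aberration_rate = 0,
                      seed = 13)
  co <- simulate_cohort(cc)
  expect_lt(abs(mean(co$clinical$event == 0) - 0.3), 0.04)
})

test_that("MSI genomes are copy-number silent", {
  cc <- cohort_config(arms = "A", n_samples_per_arm = 60, n_chromosomes = 2,
                      probes_per_chromosome = 30, msi_fraction = 0.3, seed = 9)
  co <- simulate_cohort(cc)
  msi <- co$clinical$msi
  expect_true(any(msi))
  expect_true(all(co$truth$copies[, msi] == 2L))
})

test_that("paired expression respects the target dosage correlation", {
  genes <- data.frame(gene_id = paste0("G", 1:60), chromosome = "chr1",
                      start = (0:59) * 1e5, end = (0:59) * 1e5 + 5e4)
  # rho = 0: all genes independent of CN
  p0 <- simulate_paired_expression(genes, dosage_fraction = 1, rho = 0,
                                   n_samples = 100, seed = 2)
  cors <- sapply(seq_len(60), function(g) cor(p0$cn[g, ], p0$expr[g, ]))
  expect_lt(abs(mean(cors)), 0.05)
  # near-perfect dosage: sample correlation > 0.9 at n = 141
  p1 <- simulate_paired_expression(genes[1, , drop = FALSE],
                                   dosage_fraction = 1, rho = 0.999,
                                   n_samples = 141, seed = 2)
  expect_gt(cor(p1$cn[1, ], p1$expr[1, ]), 0.9)
  expect_error(simulate_paired_expression(genes, n_samples = 2),
               "correlation undefined")
})

test_that("cell-line panel plants the requested IC50 shift", {
  regions <- data.frame(region_id = "R1", chromosome = "chr6",
                        start = 10e6, end = 20e6, type = "gain")
  p0 <- simulate_cellline_panel(300, regions, effect = c(R1 = 0), seed = 4)
  ab <- p0$truth[, "R1"]
  expect_lt(abs(median(p0$ic50$log_ic50[ab]) -
                  median(p0$ic50$log_ic50[!ab])), 0.3)
  p1 <- simulate_cellline_panel(300, regions, effect = c(R1 = -1), seed = 4)
  ab <- p1$truth[, "R1"]
  d <- median(p1$ic50$log_ic50[ab]) - median(p1$ic50$log_ic50[!ab])
  expect_lt(abs(d - (-1)), 0.3)
  # aberrant lines carry a gain segment over the region
  segs <- p1$segments[p1$segments$line_id == rownames(p1$truth)[ab][1], ]
  expect_true(any(segs$state == "gain" & segs$start < 20e6 & segs$end > 10e6))
  # CRC preset is a 31-line panel
  crc <- simulate_cellline_panel(regions = regions, effect = c(R1 = 0),
                                 panel = "CRC", seed = 1)
  expect_equal(nrow(crc$ic50), 31)
  expect_true(all(startsWith(crc$ic50$line_id, "CRC")))
  expect_error(simulate_cellline_panel(10, regions[0, ], effect = c(R1 = 0)),
               "non-empty")
})
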
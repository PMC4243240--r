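test_that("gene-region mapping uses half-open 1-bp-overlap semantics", {
  genes <- data.frame(gene_id = c("g1", "g2", "g3"),
                      chromosome = "chr1",
                      start = c(10, 10, 25), end = c(20, 20, 28))
  expect_equal(map_genes_to_region(genes[1, ],
                                   list(chromosome = "chr1", start = 19,
                                        end = 30)), "g1")
  expect_equal(length(map_genes_to_region(genes[2, ],
                                          list(chromosome = "chr1",
                                               start = 20, end = 30))), 0)
  expect_equal(map_genes_to_region(genes, list(chromosome = "chr1",
                                               start = 0, end = 100)),
               c("g1", "g2", "g3"))
  # joins are invariant to a constant coordinate shift
  shift <- 1e6
  genes2 <- transform(genes, start = start + shift, end = end + shift)
  expect_equal(map_genes_to_region(genes2, list(chromosome = "chr1",
                                                start = 19 + shift,
                                                end = 30 + shift)),
               map_genes_to_region(genes, list(chromosome = "chr1",
                                               start = 19, end = 30)))
})

test_that("dosage correlation is one-sided for positive dosage effects", {
  cn <- c(1, 1, 2, 2, 2, 3, 3, 1, 2, 3)
  dc <- dosage_correlation(cn, cn)
  expect_equal(dc$rho, 1)
  expect_lt(dc$p, 0.01)
  dcn <- dosage_correlation(cn, -cn)
  expect_equal(dcn$rho, -1)
  expect_gt(dcn$p, 0.95)
  expect_message(dz <- dosage_correlation(rep(2, 10), rnorm(10)),
                 "zero-variance")
  expect_true(is.na(dz$rho))
  expect_error(dosage_correlation(1:2, 1:2), "at least 3")
})

test_that("candidate genes are tiered by region significance and dosage", {
  # hand-built association object: R1 tier A (p<0.005 in one arm),
  # R2 tier B (p<0.05 in two arms), R3 unflagged
  results <- data.frame(
    region_id = rep(c("R1", "R2", "R3"), each = 3),
    arm = rep(c("CAP", "CAPIRI", "CAPOX-B"), 3),
    type = "gain",
    p = c(0.003, 0.4, 0.5, 0.02, 0.04, 0.6, 0.3, 0.4, 0.5),
    skipped = "", stringsAsFactors = FALSE)
  assoc <- structure(list(results = results, alpha_tier1 = 0.005,
                          alpha_tier2 = 0.05), class = "cna_assoc")
  reg <- data.frame(region_id = c("R1", "R2", "R3"), chromosome = "chr1",
                    arm = "q", start = c(0, 100, 200),
                    end = c(100, 200, 300), n_probes = 10L)
  genes <- data.frame(gene_id = c("gA", "gB", "gC", "gD"),
                      chromosome = "chr1",
                      start = c(10, 110, 120, 210), end = c(20, 120, 130, 220))
  set.seed(51)
  cn <- matrix(sample(1:3, 4 * 50, replace = TRUE), 4, 50,
               dimnames = list(genes$gene_id, NULL))
  expr <- cn + matrix(rnorm(200, 0, 0.5), 4, 50)
  expr["gC", ] <- -cn["gC", ] + rnorm(50, 0, 0.5)  # anti-dosage
  paired <- list(cn = cn[c("gA", "gB", "gC"), ], expr = expr[c("gA", "gB", "gC"), ])
  out <- select_candidate_genes(assoc, reg, genes, paired)
  expect_equal(out$tier[out$gene_id == "gA"], "A")
  expect_equal(out$status[out$gene_id == "gA"], "retained")
  expect_equal(out$tier[out$gene_id == "gB"], "B")
  expect_equal(out$status[out$gene_id == "gC"], "rejected")
  # gD sits on the unflagged region R3: absent entirely
  expect_false("gD" %in% out$gene_id)
  # genes missing from the paired data are reported untested
  paired2 <- list(cn = cn["gA", , drop = FALSE], expr = expr["gA", , drop = FALSE])
  out2 <- select_candidate_genes(assoc, reg, genes, paired2)
  expect_equal(out2$status[out2$gene_id == "gB"], "untested")
})

test_that("amplification events and recurrent loci are assembled correctly", {
  ann <- make_annotation(1, 60, spacing = 1e5)
  calls <- matrix(0L, 60, 6, dimnames = list(ann$probe_id, paste0("s", 1:6)))
  calls[11:15, 1:5] <- 2L       # shared 0.5 Mb amplicon in 5 samples
  calls[41:43, 6] <- 2L         # private amplicon elsewhere
  ev <- detect_amplicons(calls, ann)
  expect_equal(nrow(ev), 6)
  loci <- recurrent_amplicons(ev, min_freq = 4)
  expect_equal(nrow(loci), 1)
  expect_equal(loci$frequency, 5)
  expect_equal(loci$start, 1e6)  # intersection span
  expect_equal(loci$end, 1.5e6)
  # disjoint amplicons stay separate loci and are dropped below min_freq
  expect_equal(nrow(recurrent_amplicons(ev, min_freq = 1)), 2)
  # invariant to sample order
  ev2 <- ev[rev(seq_len(nrow(ev))), ]
  expect_equal(recurrent_amplicons(ev2, min_freq = 4),
               recurrent_amplicons(ev, min_freq = 4))
})

test_that("cell-line region status uses any-overlap with state matching", {
  segs <- data.frame(chromosome = "chr1",
                     start = c(0, 19.5e6), end = c(19.5e6, 25e6),
                     state = c("normal", "gain"))
  region <- list(chromosome = "chr1", start = 10e6, end = 20e6)
  expect_equal(cellline_region_status(segs, region, "gain"), "aberrant")
  expect_equal(cellline_region_status(segs, region, "loss"), "normal")
  diploid <- data.frame(chromosome = "chr1", start = 0, end = 30e6,
                        state = "normal")
  expect_equal(cellline_region_status(diploid, region, "any"), "normal")
})

test_that("Kruskal-Wallis matches hand ranking and the brute-force oracle", {
  kw <- kruskal_wallis(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(kw$H, 27 / 7, tolerance = 1e-9)  # = 3.857
  expect_equal(kw$p, pchisq(27 / 7, 1, lower.tail = FALSE))
  # whole permutation null for n1 = n2 = 4 agrees with the oracle
  set.seed(52)
  v <- c(rnorm(4), rnorm(4, 1))
  sets <- utils::combn(8, 4)
  for (c_i in sample(ncol(sets), 12)) {
    g <- rep("b", 8); g[sets[, c_i]] <- "a"
    expect_equal(kruskal_wallis(v, g)$H, brute_kw(v, g), tolerance = 1e-9)
  }
  # ties are midranked consistently with the oracle
  vt <- c(1, 1, 2, 2, 3, 3, 4, 4)
  g <- rep(c("a", "b"), 4)
  expect_equal(kruskal_wallis(vt, g)$H, brute_kw(vt, g), tolerance = 1e-9)
  expect_equal(kruskal_wallis(rep(1, 6), rep(c("a", "b"), 3))$p, 1)
  expect_error(kruskal_wallis(1:3, rep("a", 3)), "two non-empty")
})

test_that("cell-line validation recovers a planted IC50 shift", {
  regions <- data.frame(region_id = c("R1", "R2"), chromosome = "chr6",
                        start = c(10e6, 40e6), end = c(20e6, 50e6),
                        type = c("gain", "loss"))
  panel <- simulate_cellline_panel(300, regions,
                                   effect = c(R1 = -1, R2 = 0), seed = 6)
  val <- validate_regions_in_celllines(panel, regions, drug = "SN-38")
  expect_equal(nrow(val), 2)
  expect_lt(val$p[val$region_id == "R1"], 0.05)
  expect_gt(val$p[val$region_id == "R2"], 0.01)
  # restriction to a sub-panel and degenerate group sizes
  val31 <- validate_regions_in_celllines(panel, regions, drug = "SN-38",
                                         lines = panel$ic50$line_id[1:4])
  expect_true(all(val31$n_aberrant + val31$n_normal == 4))
  expect_error(validate_regions_in_celllines(panel, regions, drug = "nope"),
               "no IC50")
})
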
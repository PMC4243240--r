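#' Preprocess a cohort of copy-number profiles
#'
#' Runs the per-sample preprocessing chain in the fixed order dewave (when a
#' wave reference is supplied) -> median normalisation -> CBS segmentation
#' -> post-segmentation mode normalisation -> tumour-purity correction ->
#' four-state calling, and applies the MAD quality filter.
#'
#' @param ratios Probe x sample log2-ratio matrix.
#' @param annotation Probe annotation aligned with the rows.
#' @param purity Named per-sample tumour-cell fractions in (0, 1]; missing
#'   samples default to 1.
#' @param wave_reference Optional per-probe wave reference for [dewave()].
#' @param cbs A [cbs_params()]; per-sample permutation streams are derived
#'   from its seed.
#' @param mad_threshold QC exclusion threshold (profiles with residual MAD
#'   above it are dropped from the call matrix).
#' @param amp_max_span Maximum amplification span in bp (3 Mb rule).
#' @return A list of class `cna_cohort_calls`: `calls` (probe x sample
#'   matrix over QC-passing samples), `segments` (per-sample segment table
#'   with calls), `qc` (sample_id, mad, qc_pass), `shifts` (mode shifts),
#'   `annotation`.
#' @export
preprocess_cohort <- function(ratios, annotation, purity = NULL,
                              wave_reference = NULL, cbs = cbs_params(),
                              mad_threshold = 0.4, amp_max_span = 3e6) {
  stopifnot(nrow(ratios) == nrow(annotation))
  samples <- colnames(ratios)
  if (is.null(samples)) stop("ratios must have sample column names")
  if (is.null(purity)) purity <- setNames(rep(1, length(samples)), samples)
  if (!is.null(wave_reference))
    ratios <- dewave(ratios, wave_reference, annotation$chromosome)
  ratios <- sweep(ratios, 2, apply(ratios, 2, median))
  calls <- matrix(NA_integer_, nrow(ratios), length(samples),
                  dimnames = list(rownames(ratios), samples))
  seg_tables <- list()
  mads <- setNames(numeric(length(samples)), samples)
  shifts <- setNames(numeric(length(samples)), samples)
  for (s in samples) {
    prm <- cbs
    prm$seed <- child_seed(cbs$seed, match(s, samples))
    seg <- segment_profile(ratios[, s], annotation$chromosome, prm)
    mads[s] <- compute_mad(ratios[, s], seg$segmean_per_probe)
    mn <- mode_normalize(seg$segments, ratios[, s])
    shifts[s] <- mn$shift
    seg$segments <- mn$segments
    seg$segmean_per_probe <- rep(seg$segments$mean, seg$segments$n_probes)
    p <- if (s %in% names(purity) && !is.na(purity[s])) purity[[s]] else 1
    seg$segments$mean <- purity_correct(seg$segments$mean, p)
    called <- call_profile(seg, annotation, amp_max_span = amp_max_span)
    calls[, s] <- called$calls_per_probe
    st <- called$segments
    st$sample_id <- s
    seg_tables[[s]] <- st
  }
  qc <- qc_filter(mads, mad_threshold)
  keep <- qc$sample_id[qc$qc_pass]
  structure(list(calls = calls[, keep, drop = FALSE],
                 segments = do.call(rbind, seg_tables),
                 qc = qc, shifts = shifts, annotation = annotation),
            class = "cna_cohort_calls")
}

#' @export
print.cna_cohort_calls <- function(x, ...) {
  cat("Preprocessed cohort:", ncol(x$calls), "QC-passing samples x",
      nrow(x$calls), "probes (", sum(!x$qc$qc_pass), "excluded )\n")
  frac <- rowMeans(x$calls != 0)
  cat(sprintf("Aberrant probe fraction: median %.3f, max %.3f\n",
              median(frac), max(frac)))
  invisible(x)
}

#' Assemble a pipeline configuration
#'
#' Reads a YAML or JSON configuration (or accepts a list) describing the
#' simulation and per-stage parameters, validates it, and fills defaults.
#'
#' @param config Path to a YAML/JSON file, or a named list.
#' @param seed Overriding base seed (optional).
#' @return Validated configuration list of class `pipeline_config`.
#' @export
pipeline_config <- function(config = list(), seed = NULL) {
  if (is.character(config)) {
    config <- if (grepl("[.]json$", config)) jsonlite::read_json(config,
                                                 simplifyVector = TRUE)
      else yaml::read_yaml(config)
  }
  defaults <- list(
    cohort = list(), cbs = list(), tolerance = 0.01, B = 10000L,
    min_group = 5L, alpha_tier1 = 0.005, alpha_tier2 = 0.05, alpha = 0.05,
    min_freq = 4L, mad_threshold = 0.4, seed = 1L, build = "simulated",
    dosage = list(dosage_fraction = 0.5, rho = 0.6, n_samples = 141L),
    celllines = list(n_lines = 300L, aberrant_fraction = 0.5,
                     effect = -1, drug = "SN-38"))
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  if (!is.null(seed)) config$seed <- as.integer(seed)
  structure(config, class = "pipeline_config")
}

#' Run the end-to-end analysis pipeline on a simulated cohort
#'
#' Simulate -> preprocess -> reduce to subregions -> genome-wide
#' permutation log-rank association -> candidate-gene filtering against a
#' simulated paired expression set -> amplification catalogue -> cell-line
#' IC50 validation of the top regions. All stage outputs are written as TSV
#' under `out_dir` together with a JSON manifest carrying parameters, seeds
#' and md5 hashes of every output; a rerun with the same configuration
#' reproduces byte-identical files.
#'
#' @param config A [pipeline_config()] (or list/path acceptable to it).
#' @param out_dir Output directory (created if needed).
#' @param seed Optional base-seed override.
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir, seed = NULL) {
  config <- pipeline_config(unclass(config), seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  base_seed <- as.integer(config$seed)

  cc <- do.call(cohort_config, c(config$cohort,
                                 list(seed = child_seed(base_seed, 1L))))
  cohort <- simulate_cohort(cc)
  write_bed4(cohort$annotation, file.path(out_dir, "probes.bed"))
  write_matrix_tsv(cohort$ratios, file.path(out_dir, "ratios.tsv"))
  write.table(cohort$clinical, file.path(out_dir, "clinical.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  cbs <- do.call(cbs_params, c(config$cbs,
                               list(seed = child_seed(base_seed, 2L))))
  purity <- setNames(cohort$clinical$tumour_cell_pct / 100,
                     cohort$clinical$sample_id)
  pre <- preprocess_cohort(cohort$ratios, cohort$annotation, purity,
                           cohort$wave_reference, cbs,
                           mad_threshold = config$mad_threshold)
  write_matrix_tsv(pre$calls, file.path(out_dir, "calls.tsv"))
  seg_out <- data.frame(sample_id = pre$segments$sample_id,
                        chromosome = pre$segments$chromosome,
                        start = cohort$annotation$start[pre$segments$start_probe],
                        end = cohort$annotation$end[pre$segments$end_probe],
                        n_probes = pre$segments$n_probes,
                        seg_mean = pre$segments$mean)
  write_seg(seg_out, file.path(out_dir, "segments.seg"))
  write.table(pre$qc, file.path(out_dir, "qc.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  sub <- reduce_to_subregions(pre$calls, cohort$annotation,
                              tolerance = config$tolerance)
  write.table(cbind(sub$regions, sub$consensus),
              file.path(out_dir, "subregions.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  assoc <- associate_genomewide(sub$consensus, cohort$clinical,
                                B = config$B,
                                seed = child_seed(base_seed, 3L),
                                min_group = config$min_group,
                                alpha_tier1 = config$alpha_tier1,
                                alpha_tier2 = config$alpha_tier2)
  write.table(assoc$results, file.path(out_dir, "associations.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  # candidate genes against a simulated paired CN/expression panel:
  # one gene per subregion, placed at the subregion midpoint
  genes <- data.frame(gene_id = paste0("G_", sub$regions$region_id),
                      chromosome = sub$regions$chromosome,
                      start = (sub$regions$start + sub$regions$end) %/% 2,
                      end = (sub$regions$start + sub$regions$end) %/% 2 + 1000,
                      stringsAsFactors = FALSE)
  paired <- simulate_paired_expression(
    genes, dosage_fraction = config$dosage$dosage_fraction,
    rho = config$dosage$rho, n_samples = config$dosage$n_samples,
    seed = child_seed(base_seed, 4L))
  cand <- select_candidate_genes(assoc, sub, genes, paired,
                                 alpha = config$alpha)
  write.table(cand, file.path(out_dir, "candidate_genes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  amps <- detect_amplicons(pre$calls, cohort$annotation)
  loci <- recurrent_amplicons(amps, min_freq = config$min_freq)
  write.table(loci, file.path(out_dir, "amplicon_loci.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  # cell-line validation of the tier-1 regions (top 3 by p as a pre-declared
  # set; falls back to the 3 most aberrant regions when none is significant)
  tested <- assoc$results[assoc$results$skipped == "", , drop = FALSE]
  top <- utils::head(tested[order(tested$p), , drop = FALSE], 3)
  if (nrow(top)) {
    ridx <- match(top$region_id, sub$regions$region_id)
    vreg <- data.frame(region_id = top$region_id,
                       chromosome = sub$regions$chromosome[ridx],
                       start = sub$regions$start[ridx],
                       end = sub$regions$end[ridx],
                       type = top$type, stringsAsFactors = FALSE)
    effect <- setNames(rep(config$celllines$effect, nrow(vreg)),
                       vreg$region_id)
    panel <- simulate_cellline_panel(
      n_lines = config$celllines$n_lines, regions = vreg, effect = effect,
      seed = child_seed(base_seed, 5L),
      aberrant_fraction = config$celllines$aberrant_fraction,
      drug = config$celllines$drug)
    cl_val <- validate_regions_in_celllines(panel, vreg,
                                            drug = config$celllines$drug)
    write.table(cl_val, file.path(out_dir, "cellline_validation.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    cl_val <- NULL
  }

  files <- list.files(out_dir, pattern = "[.](tsv|seg|bed)$")
  manifest <- list(
    package = "cnsurv",
    version = as.character(utils::packageVersion("cnsurv")),
    seed = base_seed,
    parameters = unclass(config),
    hashes = as.list(tools::md5sum(file.path(out_dir, sort(files)))))
  names(manifest$hashes) <- sort(files)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(cohort = cohort, preprocessed = pre, subregions = sub,
                 association = assoc, candidate_genes = cand,
                 amplicons = loci, cellline_validation = cl_val,
                 manifest = manifest))
}
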
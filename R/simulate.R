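#' Configuration for a synthetic aCGH trial cohort
#'
#' Bundles all knobs of the cohort simulator: the genome layout (chromosomes,
#' probes, spacing), the signal model (noise, hybridisation waves, tumour
#' purity), the aberration landscape (background rate, planted driver
#' regions), and the clinical model (per-arm baseline PFS, censoring, MSI
#' fraction).
#'
#' Defaults emulate a three-arm metastatic colorectal cancer trial cohort at
#' desk scale: arm sizes 105/111/133, probes at ~17 kb spacing, log2-ratio
#' noise sd 0.15, wave amplitude 0.10, tumour purity 0.7--1, about 8
#' background aberrant segments per genome, exponential PFS with arm medians
#' 180/240/320 days, 20% censoring and a 6% MSI fraction with near-silent
#' genomes.
#'
#' @param arms Character vector of treatment-arm labels.
#' @param n_samples_per_arm Integer vector, samples per arm (recycled against
#'   `arms`).
#' @param n_chromosomes Number of simulated chromosomes.
#' @param probes_per_chromosome Probes tiled per chromosome.
#' @param probe_spacing Probe spacing in bp; probe k spans
#'   `[(k-1)*spacing, k*spacing)`.
#' @param noise_sd Per-probe Gaussian noise sd, log2 units.
#' @param wave_amplitude Amplitude of the per-chromosome sinusoidal wave,
#'   log2 units.
#' @param wave_period Wave period in probes.
#' @param purity_range Tumour-cell-fraction interval, subset of (0, 1].
#' @param background_aberration_rate Expected number of background aberrant
#'   segments per (non-MSI) genome.
#' @param driver_regions List of [driver_spec()] objects.
#' @param baseline_median_pfs Numeric vector of per-arm baseline median PFS in
#'   days (recycled against `arms`).
#' @param censoring_rate Target fraction of censored samples, in [0, 1).
#' @param msi_fraction Fraction of microsatellite-instable samples; their
#'   genomes are copy-number silent.
#' @param seed Integer seed; every stochastic output is reproducible from it.
#' @return A list of class `cohort_config`.
#' @seealso [simulate_cohort()], [driver_spec()]
#' @export
cohort_config <- function(arms = c("CAP", "CAPIRI", "CAPOX-B"),
                          n_samples_per_arm = c(105L, 111L, 133L),
                          n_chromosomes = 4L,
                          probes_per_chromosome = 250L,
                          probe_spacing = 17000,
                          noise_sd = 0.15,
                          wave_amplitude = 0.10,
                          wave_period = 50,
                          purity_range = c(0.7, 1),
                          background_aberration_rate = 8,
                          driver_regions = list(),
                          baseline_median_pfs = c(180, 240, 320),
                          censoring_rate = 0.2,
                          msi_fraction = 0.06,
                          seed = 1L) {
  stopifnot(length(arms) >= 1, !anyDuplicated(arms))
  n_samples_per_arm <- rep_len(as.integer(n_samples_per_arm), length(arms))
  baseline_median_pfs <- rep_len(as.numeric(baseline_median_pfs), length(arms))
  if (any(n_samples_per_arm <= 0)) stop("n_samples_per_arm must be positive")
  if (n_chromosomes <= 0 || probes_per_chromosome <= 0 || probe_spacing <= 0)
    stop("genome layout counts must be positive")
  if (length(purity_range) != 2 || purity_range[1] <= 0 ||
      purity_range[2] > 1 || purity_range[1] > purity_range[2])
    stop("purity_range must be an interval within (0, 1]")
  if (censoring_rate < 0 || censoring_rate >= 1)
    stop("censoring_rate must be in [0, 1)")
  if (any(baseline_median_pfs <= 0)) stop("baseline_median_pfs must be positive")
  if (msi_fraction < 0 || msi_fraction >= 1)
    stop("msi_fraction must be in [0, 1)")
  if (wave_period <= 0) stop("wave_period must be positive")
  for (d in driver_regions) {
    if (!inherits(d, "driver_spec")) stop("driver_regions must contain driver_spec objects")
  }
  structure(list(
    arms = arms, n_samples_per_arm = setNames(n_samples_per_arm, arms),
    n_chromosomes = as.integer(n_chromosomes),
    probes_per_chromosome = as.integer(probes_per_chromosome),
    probe_spacing = probe_spacing, noise_sd = noise_sd,
    wave_amplitude = wave_amplitude, wave_period = wave_period,
    purity_range = purity_range,
    background_aberration_rate = background_aberration_rate,
    driver_regions = driver_regions,
    baseline_median_pfs = setNames(baseline_median_pfs, arms),
    censoring_rate = censoring_rate, msi_fraction = msi_fraction,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

#' Specify a planted driver aberration
#'
#' A driver is an aberration (`loss`, `gain` or `amplification`) placed on a
#' fixed genomic interval in a random subset of samples; carrying it
#' multiplies the sample's progression hazard by an arm-specific hazard
#' ratio. Drivers are the ground truth against which association power and
#' parameter recovery are measured.
#'
#' @param chromosome Chromosome label (e.g. `"chr1"`).
#' @param start,end Interval in bp, 0-based half-open, `start < end`.
#' @param aberration One of `"loss"`, `"gain"`, `"amplification"`.
#' @param carrier_fraction Fraction of (non-MSI) samples carrying the driver,
#'   in (0, 1).
#' @param hazard_ratio_per_arm Named positive numeric, hazard ratio of
#'   carriers per arm; arms not named get HR 1.
#' @return A list of class `driver_spec`.
#' @export
driver_spec <- function(chromosome, start, end,
                        aberration = c("loss", "gain", "amplification"),
                        carrier_fraction, hazard_ratio_per_arm) {
  aberration <- match.arg(aberration)
  if (start >= end) stop("driver start must be < end")
  if (carrier_fraction <= 0 || carrier_fraction >= 1)
    stop("carrier_fraction must be in (0, 1)")
  if (any(hazard_ratio_per_arm <= 0)) stop("hazard ratios must be positive")
  structure(list(chromosome = chromosome, start = start, end = end,
                 aberration = aberration,
                 carrier_fraction = carrier_fraction,
                 hazard_ratio_per_arm = hazard_ratio_per_arm),
            class = "driver_spec")
}

#' Simulate the probe annotation of a tiling array
#'
#' Probes tile each chromosome contiguously at `probe_spacing` bp: probe k of
#' a chromosome spans `[(k-1)*spacing, k*spacing)` (0-based half-open).
#' Deterministic given the configuration.
#'
#' @param config A [cohort_config()].
#' @return A data.frame with columns `chromosome`, `start`, `end`,
#'   `probe_id`, sorted by (chromosome, start); chromosomes are ordered
#'   `chr1..chrN`.
#' @export
simulate_probe_annotation <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  m <- config$probes_per_chromosome
  chroms <- paste0("chr", seq_len(config$n_chromosomes))
  ann <- do.call(rbind, lapply(chroms, function(ch) {
    k <- seq_len(m)
    data.frame(chromosome = ch,
               start = (k - 1) * config$probe_spacing,
               end = k * config$probe_spacing,
               probe_id = sprintf("%s_P%05d", ch, k),
               stringsAsFactors = FALSE)
  }))
  rownames(ann) <- ann$probe_id
  ann
}

# Copy-number alphabet of the simulator: integer copies mapping onto the four
# call states (0/1 loss, 2 normal, 3 gain, 6 amplification).
.copies_for <- function(aberration) {
  switch(aberration, loss = 1L, gain = 3L, amplification = 6L)
}

#' Simulate a full trial cohort with ground truth
#'
#' Generates, per sample, a piecewise-constant integer copy-number profile
#' (background aberrations plus planted drivers), observed as purity-diluted
#' log2 ratios with a per-chromosome sinusoidal wave and Gaussian noise:
#' `r = log2(p*c/2 + (1-p)) + wave + noise`. Progression-free survival is
#' exponential with arm-specific baseline rate multiplied by the hazard
#' ratios of carried drivers; censoring is independent exponential with the
#' rate tuned by bisection to the target censoring fraction. MSI samples get
#' copy-number-silent genomes (no background aberrations, no drivers).
#'
#' A wave reference -- the average profile of 20 simulated copy-number-normal
#' samples hybridised with the same wave and noise -- is returned for use by
#' [dewave()].
#'
#' @param config A [cohort_config()].
#' @return A list of class `cna_cohort`: `annotation`, `ratios` (probe x
#'   sample log2-ratio matrix), `clinical` (data.frame with sample_id, arm,
#'   pfs_days, event, cycles, death_progression, msi, tumour_cell_pct),
#'   `wave_reference`, and `truth` (copies matrix, per-driver carrier flags,
#'   purity, event records).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  ann <- simulate_probe_annotation(config)
  P <- nrow(ann)
  chroms <- unique(ann$chromosome)
  chrom_len <- config$probes_per_chromosome * config$probe_spacing
  for (d in config$driver_regions) {
    if (!(d$chromosome %in% chroms) || d$end > chrom_len)
      stop("driver region outside the simulated genome")
  }
  n <- sum(config$n_samples_per_arm)
  arm <- rep(config$arms, config$n_samples_per_arm)
  sample_id <- sprintf("S%04d", seq_len(n))

  with_seed(config$seed, {
    purity <- runif(n, config$purity_range[1], config$purity_range[2])
    msi <- as.logical(rbinom(n, 1, config$msi_fraction))

    copies <- matrix(2L, P, n, dimnames = list(ann$probe_id, sample_id))
    events <- list()
    probe_chrom <- ann$chromosome
    for (s in seq_len(n)) {
      if (msi[s]) next
      n_ev <- rpois(1, config$background_aberration_rate)
      for (e in seq_len(n_ev)) {
        ch <- sample(chroms, 1)
        type <- sample(c("loss", "gain", "amplification"), 1,
                       prob = c(0.45, 0.45, 0.10))
        idx <- which(probe_chrom == ch)
        m <- length(idx)
        if (type == "amplification") {
          span_bp <- runif(1, config$probe_spacing, min(3e6, chrom_len / 2))
          len <- max(1L, as.integer(span_bp / config$probe_spacing))
        } else {
          # broad events cover 3-20% of a chromosome; with the default rate
          # and genome this keeps the aberrant genome fraction near 25%,
          # preserving the dominant-diploid state that mode normalisation
          # (and any absolute-level anchoring) requires
          len <- max(1L, as.integer(runif(1, 0.03, 0.2) * m))
        }
        st <- sample.int(m - len + 1L, 1)
        rows <- idx[st:(st + len - 1L)]
        copies[rows, s] <- .copies_for(type)
        events[[length(events) + 1L]] <-
          data.frame(sample_id = sample_id[s], chromosome = ch,
                     start = ann$start[rows[1]], end = ann$end[rows[length(rows)]],
                     aberration = type, stringsAsFactors = FALSE)
      }
    }

    n_drv <- length(config$driver_regions)
    carriers <- matrix(FALSE, n, n_drv,
                       dimnames = list(sample_id,
                                       if (n_drv) paste0("driver", seq_len(n_drv))))
    for (k in seq_len(n_drv)) {
      d <- config$driver_regions[[k]]
      eligible <- which(!msi)
      flag <- as.logical(rbinom(length(eligible), 1, d$carrier_fraction))
      if (!any(flag))
        warning(sprintf("driver %d: no carriers drawn (carrier_fraction %.3g, n %d)",
                        k, d$carrier_fraction, length(eligible)))
      carriers[eligible[flag], k] <- TRUE
      rows <- which(probe_chrom == d$chromosome &
                      ann$start < d$end & ann$end > d$start)
      copies[rows, carriers[, k]] <- .copies_for(d$aberration)
    }

    wave <- config$wave_amplitude *
      sin(2 * pi * ave(seq_len(P), probe_chrom, FUN = seq_along) /
            config$wave_period)
    eps <- 2^-10
    lin <- sweep(copies / 2, 2, purity, "*") + rep(1 - purity, each = P)
    ratios <- log2(pmax(lin, eps)) + wave +
      matrix(rnorm(P * n, 0, config$noise_sd), P, n)
    dimnames(ratios) <- list(ann$probe_id, sample_id)

    n_ref <- 20L
    ref <- wave + matrix(rnorm(P * n_ref, 0, config$noise_sd), P, n_ref)
    wave_reference <- rowMeans(ref)

    # survival: exponential PFS, multiplicative driver hazards
    lambda <- log(2) / config$baseline_median_pfs[arm]
    if (n_drv) {
      for (k in seq_len(n_drv)) {
        hr <- config$driver_regions[[k]]$hazard_ratio_per_arm
        mult <- ifelse(arm %in% names(hr), hr[arm], 1)
        mult[is.na(mult)] <- 1
        lambda <- lambda * ifelse(carriers[, k], mult, 1)
      }
    }
    t_event <- rexp(n, lambda)
    if (config$censoring_rate > 0) {
      target <- config$censoring_rate
      f <- function(cr) mean(cr / (cr + lambda)) - target
      lo <- 1e-9; hi <- max(lambda) * 1e3
      for (it in 1:200) {
        mid <- sqrt(lo * hi)
        if (f(mid) < 0) lo <- mid else hi <- mid
        if (hi / lo < 1 + 1e-12) break
      }
      cens_rate <- sqrt(lo * hi)
      t_cens <- rexp(n, cens_rate)
    } else {
      t_cens <- rep(Inf, n)
    }
    pfs <- pmin(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)

    cycles <- 3L + rpois(n, 2)
    few <- as.logical(rbinom(n, 1, 0.08))
    cycles[few] <- 2L
    death_progression <- few & event == 1L & pfs < median(pfs)

    clinical <- data.frame(
      sample_id = sample_id, arm = arm, pfs_days = round(pfs, 1),
      event = event, cycles = cycles,
      death_progression = death_progression, msi = msi,
      tumour_cell_pct = round(purity * 100, 1),
      stringsAsFactors = FALSE)

    truth <- list(
      copies = copies, purity = purity, carriers = carriers,
      events = if (length(events)) do.call(rbind, events) else NULL,
      lambda = lambda, wave = wave, seed = config$seed)

    structure(list(annotation = ann, ratios = ratios, clinical = clinical,
                   wave_reference = wave_reference, truth = truth,
                   config = config),
              class = "cna_cohort")
  })
}

#' @export
print.cna_cohort <- function(x, ...) {
  cat("Synthetic aCGH cohort:",
      ncol(x$ratios), "samples x", nrow(x$ratios), "probes\n")
  cat("Arms:", paste(sprintf("%s (n=%d)", x$config$arms,
                             x$config$n_samples_per_arm), collapse = ", "), "\n")
  cat("Drivers:", length(x$config$driver_regions),
      " MSI samples:", sum(x$clinical$msi), "\n")
  invisible(x)
}

#' Simulate a paired copy-number / expression data set
#'
#' A fraction of genes is dosage-sensitive: their expression is a linear
#' function of the per-sample copy number plus Gaussian noise calibrated so
#' that the population Pearson correlation equals `rho`. The remaining genes
#' get expression independent of copy number. Per-sample gene copy numbers
#' are drawn i.i.d. from {1, 2, 3} with probabilities (0.25, 0.5, 0.25).
#'
#' @param genes Gene annotation data.frame (`gene_id`, `chromosome`, `start`,
#'   `end`).
#' @param dosage_fraction Fraction of genes that are dosage-sensitive.
#' @param rho Target population correlation for dosage genes, in [0, 1).
#' @param n_samples Number of paired samples (default 141, a typical paired
#'   CRC panel size); must be >= 3.
#' @param seed Integer seed.
#' @return A list of class `paired_expression`: `cn` and `expr` (gene x
#'   sample matrices) and `truth` (character vector of dosage-sensitive
#'   gene_ids).
#' @export
simulate_paired_expression <- function(genes, dosage_fraction = 0.5,
                                       rho = 0.6, n_samples = 141L,
                                       seed = 1L) {
  if (rho < 0 || rho >= 1) stop("rho must be in [0, 1)")
  if (n_samples < 3) stop("n_samples must be >= 3 (correlation undefined)")
  g <- nrow(genes)
  if (g == 0) stop("no genes supplied")
  with_seed(seed, {
    cn <- matrix(sample(c(1, 2, 3), g * n_samples, replace = TRUE,
                        prob = c(0.25, 0.5, 0.25)),
                 g, n_samples, dimnames = list(genes$gene_id, NULL))
    colnames(cn) <- sprintf("T%04d", seq_len(n_samples))
    n_dosage <- round(dosage_fraction * g)
    dosage <- sample(genes$gene_id, n_dosage)
    var_cn <- 0.5  # variance of the {1,2,3} copy distribution
    expr <- matrix(rnorm(g * n_samples), g, n_samples, dimnames = dimnames(cn))
    if (n_dosage && rho > 0) {
      noise_sd <- sqrt(var_cn * (1 / rho^2 - 1))
      idx <- rownames(cn) %in% dosage
      expr[idx, ] <- cn[idx, ] +
        matrix(rnorm(sum(idx) * n_samples, 0, noise_sd), sum(idx), n_samples)
    }
    structure(list(cn = cn, expr = expr, truth = sort(dosage), seed = seed),
              class = "paired_expression")
  })
}

#' Simulate a cell-line copy-number / drug-sensitivity panel
#'
#' Each line is assigned, per tested region, an aberrant status with
#' probability `aberrant_fraction`; aberrant lines receive a copy-number
#' segment of the region's aberration type covering the region, and their
#' log-IC50 for the drug is shifted by the region's `effect`. Non-aberrant
#' chromosomes are covered by diploid segments. Baseline log-IC50 is
#' N(0, `ic50_sd`).
#'
#' @param n_lines Number of cell lines; with `panel = "CRC"` defaults to 31
#'   (a colorectal-panel-sized set, lines labelled `CRC...`).
#' @param regions Data.frame of tested regions: `region_id`, `chromosome`,
#'   `start`, `end`, `type` (`"gain"` or `"loss"`); must be non-empty.
#' @param effect Named numeric of log-IC50 shifts keyed by `region_id`.
#' @param seed Integer seed.
#' @param aberrant_fraction Probability a line is aberrant for a region.
#' @param ic50_sd Baseline log-IC50 standard deviation.
#' @param drug Drug label attached to the IC50 table.
#' @param panel `"custom"` or `"CRC"` (31-line colorectal preset).
#' @param chrom_lengths Optional named chromosome lengths (bp); defaults to
#'   1.5x the furthest region end per chromosome.
#' @return A list of class `cellline_panel`: `segments` (line_id, chromosome,
#'   start, end, copy_number, state), `ic50` (line_id, drug, log_ic50) and
#'   `truth` (line x region aberrant-status matrix).
#' @export
simulate_cellline_panel <- function(n_lines = NULL, regions, effect,
                                    seed = 1L, aberrant_fraction = 0.5,
                                    ic50_sd = 1, drug = "SN-38",
                                    panel = c("custom", "CRC"),
                                    chrom_lengths = NULL) {
  panel <- match.arg(panel)
  if (is.null(n_lines)) n_lines <- if (panel == "CRC") 31L else 300L
  if (is.null(regions) || nrow(regions) == 0) stop("regions must be non-empty")
  stopifnot(all(c("region_id", "chromosome", "start", "end", "type") %in%
                  names(regions)))
  if (!all(regions$region_id %in% names(effect)))
    stop("effect must be keyed by region_id")
  prefix <- if (panel == "CRC") "CRC" else "CL"
  line_id <- sprintf("%s%03d", prefix, seq_len(n_lines))
  chroms <- unique(regions$chromosome)
  if (is.null(chrom_lengths)) {
    chrom_lengths <- sapply(chroms, function(ch)
      1.5 * max(regions$end[regions$chromosome == ch]))
  }
  with_seed(seed, {
    status <- matrix(as.logical(rbinom(n_lines * nrow(regions), 1,
                                       aberrant_fraction)),
                     n_lines, nrow(regions),
                     dimnames = list(line_id, regions$region_id))
    segs <- list()
    for (l in seq_len(n_lines)) {
      for (ch in chroms) {
        ridx <- which(regions$chromosome == ch)
        # aberrant regions become dedicated segments; the rest diploid
        ab <- ridx[status[l, ridx]]
        ab <- ab[order(regions$start[ab])]
        pos <- 0
        for (r in ab) {
          if (regions$start[r] > pos) {
            segs[[length(segs) + 1L]] <- data.frame(
              line_id = line_id[l], chromosome = ch, start = pos,
              end = regions$start[r], copy_number = 2, state = "normal")
          }
          cnv <- if (regions$type[r] == "gain") 3 else 1
          segs[[length(segs) + 1L]] <- data.frame(
            line_id = line_id[l], chromosome = ch, start = regions$start[r],
            end = regions$end[r], copy_number = cnv, state = regions$type[r])
          pos <- regions$end[r]
        }
        if (pos < chrom_lengths[[ch]]) {
          segs[[length(segs) + 1L]] <- data.frame(
            line_id = line_id[l], chromosome = ch, start = pos,
            end = chrom_lengths[[ch]], copy_number = 2, state = "normal")
        }
      }
    }
    segments <- do.call(rbind, segs)
    shift <- as.numeric(status %*% effect[regions$region_id])
    ic50 <- data.frame(line_id = line_id, drug = drug,
                       log_ic50 = rnorm(n_lines, 0, ic50_sd) + shift,
                       stringsAsFactors = FALSE)
    structure(list(segments = segments, ic50 = ic50, truth = status,
                   seed = seed),
              class = "cellline_panel")
  })
}
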
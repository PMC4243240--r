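# All genomic intervals in this package are 0-based half-open; two intervals
# overlap iff start1 < end2 && start2 < end1 (>= 1 bp shared).
.overlaps <- function(s1, e1, s2, e2) s1 < e2 & s2 < e1

#' Map genes onto a genomic region
#'
#' Returns the genes overlapping the region by at least 1 bp, half-open
#' interval semantics on both sides.
#'
#' @param genes Gene annotation data.frame (`gene_id`, `chromosome`,
#'   `start`, `end`; 0-based half-open).
#' @param region A list or one-row data.frame with `chromosome`, `start`,
#'   `end`.
#' @return Character vector of overlapping `gene_id`s.
#' @export
map_genes_to_region <- function(genes, region) {
  hit <- genes$chromosome == region$chromosome &
    .overlaps(genes$start, genes$end, region$start, region$end)
  genes$gene_id[hit]
}

#' Dosage sensitivity of one gene: copy-number vs expression correlation
#'
#' Spearman rank correlation between a gene's copy-number values and its
#' expression across samples, with a one-sided p-value for positive
#' correlation (dosage effect). A zero-variance copy-number vector makes the
#' correlation undefined: `NA` is returned and such genes are not retained
#' downstream.
#'
#' @param cn Per-sample copy-number values (segment means or calls).
#' @param expr Per-sample expression values.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return List with `rho` and one-sided `p`.
#' @export
dosage_correlation <- function(cn, expr, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  ok <- complete.cases(cn, expr)
  cn <- cn[ok]; expr <- expr[ok]
  if (length(cn) < 3) stop("need at least 3 paired samples")
  if (var(cn) == 0 || var(expr) == 0) {
    message("dosage_correlation: zero-variance input, correlation undefined")
    return(list(rho = NA_real_, p = NA_real_))
  }
  ct <- suppressWarnings(cor.test(cn, expr, method = method,
                                  alternative = "greater", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Select candidate dosage-sensitive genes on survival-associated regions
#'
#' Genes are first restricted to survival-associated regions: tier A regions
#' have a permutation p below `alpha_tier1` in at least one arm for an
#' aberration type; tier B regions have p below `alpha_tier2` in at least
#' two arms for the same type. Genes overlapping a qualifying subregion are
#' then tested for a positive copy-number--expression correlation in the
#' paired data set and retained when the one-sided p is below `alpha` with
#' `rho > 0`. Genes missing from the paired data are reported `untested`.
#'
#' @param assoc A `cna_assoc` from [associate_genomewide()].
#' @param subregions A `cna_subregions` (for region coordinates).
#' @param genes Gene annotation data.frame.
#' @param paired A `paired_expression` (or list with `cn`, `expr` gene x
#'   sample matrices).
#' @param alpha Dosage-correlation significance level (default 0.05).
#' @param alpha_tier1,alpha_tier2 Region significance tiers (defaults
#'   0.005 / 0.05; override the thresholds stored in `assoc` if given).
#' @return Data.frame: `gene_id`, `region_id`, `tier` ("A"/"B"), `rho`, `p`,
#'   `status` ("retained", "rejected", "untested").
#' @export
select_candidate_genes <- function(assoc, subregions, genes, paired,
                                   alpha = 0.05,
                                   alpha_tier1 = NULL, alpha_tier2 = NULL) {
  stopifnot(inherits(assoc, "cna_assoc"))
  if (is.null(alpha_tier1)) alpha_tier1 <- assoc$alpha_tier1
  if (is.null(alpha_tier2)) alpha_tier2 <- assoc$alpha_tier2
  res <- assoc$results
  res <- res[res$skipped == "", , drop = FALSE]
  key <- paste(res$region_id, res$type)
  tierA_regions <- unique(res$region_id[res$p < alpha_tier1])
  hit2 <- tapply(res$p < alpha_tier2, key, sum)
  tierB_keys <- names(hit2)[hit2 >= 2]
  tierB_regions <- unique(sub(" .*$", "", tierB_keys))
  reg <- if (inherits(subregions, "cna_subregions")) subregions$regions
         else subregions
  out <- list()
  for (rid in union(tierA_regions, tierB_regions)) {
    rrow <- reg[reg$region_id == rid, , drop = FALSE]
    if (nrow(rrow) == 0) next
    tier <- if (rid %in% tierA_regions) "A" else "B"
    for (gid in map_genes_to_region(genes, rrow[1, ])) {
      if (!(gid %in% rownames(paired$cn)) ||
          !(gid %in% rownames(paired$expr))) {
        out[[length(out) + 1L]] <- data.frame(
          gene_id = gid, region_id = rid, tier = tier,
          rho = NA_real_, p = NA_real_, status = "untested",
          stringsAsFactors = FALSE)
        next
      }
      dc <- dosage_correlation(paired$cn[gid, ], paired$expr[gid, ])
      status <- if (!is.na(dc$p) && dc$p < alpha && dc$rho > 0)
        "retained" else "rejected"
      out[[length(out) + 1L]] <- data.frame(
        gene_id = gid, region_id = rid, tier = tier,
        rho = dc$rho, p = dc$p, status = status, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(gene_id = character(), region_id = character(),
                      tier = character(), rho = numeric(), p = numeric(),
                      status = character(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Detect amplification events in a called matrix
#'
#' Per sample, maximal runs of amplification calls (+2) form events. (Calls
#' are made after the 3 Mb downgrade rule, so every event spans at most
#' 3 Mb.)
#'
#' @param calls Probe x sample call matrix.
#' @param annotation Probe annotation aligned with the rows.
#' @return Data.frame of events: `sample_id`, `chromosome`, `start`, `end`,
#'   `n_probes`.
#' @export
detect_amplicons <- function(calls, annotation) {
  out <- list()
  samples <- colnames(calls)
  if (is.null(samples)) samples <- sprintf("S%04d", seq_len(ncol(calls)))
  for (s in seq_len(ncol(calls))) {
    for (ch in unique(annotation$chromosome)) {
      idx <- which(annotation$chromosome == ch)
      amp <- calls[idx, s] == 2L
      if (!any(amp)) next
      r <- rle(amp)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (k in which(r$values)) {
        rows <- idx[starts[k]:ends[k]]
        out[[length(out) + 1L]] <- data.frame(
          sample_id = samples[s], chromosome = ch,
          start = annotation$start[rows[1]],
          end = annotation$end[rows[length(rows)]],
          n_probes = length(rows), stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(sample_id = character(), chromosome = character(),
                      start = numeric(), end = numeric(),
                      n_probes = integer(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Group amplification events into recurrent loci
#'
#' Events are grouped per chromosome by single-linkage on >= 1 bp overlap
#' (connected components of the interval-overlap graph). Locus frequency is
#' the number of distinct samples contributing events; the locus span is the
#' intersection of its member events, falling back to their union (flagged)
#' when the intersection is empty. Loci at or above `min_freq` are reported,
#' sorted by frequency then coordinate. Results are invariant to sample
#' ordering.
#'
#' @param events Event table from [detect_amplicons()].
#' @param min_freq Minimum number of distinct samples (default 4).
#' @return Data.frame: `chromosome`, `start`, `end`, `frequency`,
#'   `n_events`, `span_is_union`.
#' @export
recurrent_amplicons <- function(events, min_freq = 4L) {
  empty <- data.frame(chromosome = character(), start = numeric(),
                      end = numeric(), frequency = integer(),
                      n_events = integer(), span_is_union = logical(),
                      stringsAsFactors = FALSE)
  if (nrow(events) == 0) return(empty)
  out <- list()
  for (ch in unique(events$chromosome)) {
    ev <- events[events$chromosome == ch, , drop = FALSE]
    ev <- ev[order(ev$start, ev$end, ev$sample_id), , drop = FALSE]
    # sweep: a new component starts when the next event does not overlap
    # the running maximum end
    comp <- integer(nrow(ev))
    cur <- 1L; max_end <- ev$end[1]; comp[1] <- 1L
    for (i in seq_len(nrow(ev))[-1]) {
      if (ev$start[i] < max_end) {
        comp[i] <- cur
        max_end <- max(max_end, ev$end[i])
      } else {
        cur <- cur + 1L
        comp[i] <- cur
        max_end <- ev$end[i]
      }
    }
    for (g in split(seq_len(nrow(ev)), comp)) {
      is_start <- max(ev$start[g]); is_end <- min(ev$end[g])
      union_empty <- is_start >= is_end
      out[[length(out) + 1L]] <- data.frame(
        chromosome = ch,
        start = if (union_empty) min(ev$start[g]) else is_start,
        end = if (union_empty) max(ev$end[g]) else is_end,
        frequency = length(unique(ev$sample_id[g])),
        n_events = length(g), span_is_union = union_empty,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res <- res[res$frequency >= min_freq, , drop = FALSE]
  if (nrow(res) == 0) return(empty)
  res <- res[order(-res$frequency, res$chromosome, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Aberration status of a cell line over a region
#'
#' A line is aberrant for the region if any of its copy-number segments in
#' the tested state overlaps the region by at least 1 bp; otherwise normal.
#' With `type = "any"`, gain and loss segments both count as aberrant.
#'
#' @param segments One line's segment data.frame (`chromosome`, `start`,
#'   `end`, `state` in {"loss", "normal", "gain"}).
#' @param region List/one-row data.frame with `chromosome`, `start`, `end`.
#' @param type `"gain"`, `"loss"` or `"any"`.
#' @return `"aberrant"` or `"normal"`.
#' @export
cellline_region_status <- function(segments, region,
                                   type = c("gain", "loss", "any")) {
  type <- match.arg(type)
  states <- if (type == "any") c("gain", "loss") else type
  hit <- segments$chromosome == region$chromosome &
    segments$state %in% states &
    .overlaps(segments$start, segments$end, region$start, region$end)
  if (any(hit)) "aberrant" else "normal"
}

#' Kruskal-Wallis rank test
#'
#' Midrank-based H with tie correction and a chi-square (k-1 df) p-value.
#' When all values are identical the statistic is 0 and p = 1.
#'
#' @param values Numeric response (e.g. log-IC50).
#' @param groups Group labels; at least two non-empty groups.
#' @return List with `H`, `df`, `p`.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(droplevels(groups)) < 2)
    stop("need at least two non-empty groups")
  if (length(unique(values)) == 1L)
    return(list(H = 0, df = nlevels(droplevels(groups)) - 1L, p = 1))
  kt <- kruskal.test(values, droplevels(groups))
  list(H = unname(kt$statistic), df = unname(kt$parameter), p = kt$p.value)
}

#' Validate survival-associated regions against cell-line drug sensitivity
#'
#' Classifies every cell line of the panel as aberrant or normal for each
#' region ([cellline_region_status()]) and tests whether the drug's log-IC50
#' distribution differs between the two status groups with a Kruskal-Wallis
#' test. Intended for a small pre-declared region set, so p-values are
#' uncorrected (alpha 0.05 by convention). Regions with fewer than two lines
#' in either group are reported `NA`.
#'
#' @param panel A `cellline_panel` (or list with `segments` and `ic50`).
#' @param regions Data.frame of regions (`region_id`, `chromosome`, `start`,
#'   `end`, and optionally `type`).
#' @param drug Drug name to look up in the IC50 table.
#' @param lines Optional subset of line ids (e.g. a tissue sub-panel).
#' @return Data.frame: `region_id`, `n_aberrant`, `n_normal`, `H`, `p`.
#' @export
validate_regions_in_celllines <- function(panel, regions, drug,
                                          lines = NULL) {
  ic50 <- panel$ic50[panel$ic50$drug == drug, , drop = FALSE]
  if (nrow(ic50) == 0) stop("no IC50 data for drug ", drug)
  if (!is.null(lines)) ic50 <- ic50[ic50$line_id %in% lines, , drop = FALSE]
  segs <- split(panel$segments, panel$segments$line_id)
  out <- list()
  for (r in seq_len(nrow(regions))) {
    region <- regions[r, , drop = FALSE]
    type <- if ("type" %in% names(regions)) region$type else "any"
    status <- vapply(ic50$line_id, function(l) {
      sl <- segs[[l]]
      if (is.null(sl)) "normal"
      else cellline_region_status(sl, region, type = type)
    }, character(1))
    n_ab <- sum(status == "aberrant")
    n_no <- sum(status == "normal")
    if (n_ab < 2 || n_no < 2) {
      out[[r]] <- data.frame(region_id = region$region_id,
                             n_aberrant = n_ab, n_normal = n_no,
                             H = NA_real_, p = NA_real_,
                             stringsAsFactors = FALSE)
    } else {
      kw <- kruskal_wallis(ic50$log_ic50, status)
      out[[r]] <- data.frame(region_id = region$region_id,
                             n_aberrant = n_ab, n_normal = n_no,
                             H = kw$H, p = kw$p, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
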
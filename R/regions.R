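#' Reduce a probe x sample call matrix to chromosomal subregions
#'
#' Greedy left-to-right scan per chromosome: the current subregion is
#' extended to the next probe while the fraction of samples whose call at
#' that probe differs from the subregion's consensus signature stays within
#' `tolerance`; otherwise a new subregion starts. The consensus signature is
#' the per-sample modal call over member probes. Subregions never span
#' chromosomes; at tolerance 0 the reduction is lossless (every probe call
#' equals its subregion consensus).
#'
#' Chromosome arms are assigned from a centromere table (p if the subregion
#' midpoint lies left of the centromere); without one the centromere is
#' placed at the chromosome midpoint.
#'
#' @param calls Integer probe x sample matrix with values in {-1, 0, 1, 2},
#'   probes ordered genomically.
#' @param annotation Probe annotation data.frame aligned with the rows of
#'   `calls` (`chromosome`, `start`, `end`).
#' @param tolerance Allowed per-probe fraction of samples deviating from the
#'   consensus, in [0, 0.2].
#' @param centromeres Optional data.frame (`chromosome`, `position` in bp).
#' @return A list of class `cna_subregions`: `regions` (data.frame:
#'   `region_id`, `chromosome`, `arm`, `start`, `end`, `n_probes`),
#'   `consensus` (region x sample call matrix), `probe_region` (per-probe
#'   region index) and `reconstruction_error`.
#' @export
reduce_to_subregions <- function(calls, annotation, tolerance = 0.01,
                                 centromeres = NULL) {
  if (is.null(dim(calls)) || nrow(calls) == 0 || ncol(calls) == 0)
    stop("calls must be a non-empty probe x sample matrix")
  if (tolerance < 0 || tolerance > 0.2) stop("tolerance must be in [0, 0.2]")
  if (nrow(annotation) != nrow(calls))
    stop("annotation must align with the rows of calls")
  n <- ncol(calls)
  states <- c(-1L, 0L, 1L, 2L)
  probe_region <- integer(nrow(calls))
  reg_rows <- list()
  cons_rows <- list()
  rid <- 0L
  for (ch in unique(annotation$chromosome)) {
    idx <- which(annotation$chromosome == ch)
    start_i <- idx[1]
    # per-sample state counts of the open subregion (4 x n)
    counts <- matrix(0L, 4L, n)
    counts[cbind(match(calls[idx[1], ], states), seq_len(n))] <- 1L
    consensus <- calls[idx[1], ]
    close_region <- function(first, last, consensus) {
      rid <<- rid + 1L
      reg_rows[[rid]] <<- data.frame(
        region_id = NA_character_, chromosome = ch,
        start = annotation$start[first], end = annotation$end[last],
        n_probes = last - first + 1L, stringsAsFactors = FALSE)
      cons_rows[[rid]] <<- consensus
      probe_region[first:last] <<- rid
    }
    prev <- idx[1]
    for (i in idx[-1]) {
      differ <- mean(calls[i, ] != consensus)
      if (differ <= tolerance) {
        counts[cbind(match(calls[i, ], states), seq_len(n))] <-
          counts[cbind(match(calls[i, ], states), seq_len(n))] + 1L
        consensus <- states[max.col(t(counts), ties.method = "first")]
        prev <- i
      } else {
        close_region(start_i, prev, consensus)
        start_i <- i
        counts <- matrix(0L, 4L, n)
        counts[cbind(match(calls[i, ], states), seq_len(n))] <- 1L
        consensus <- calls[i, ]
        prev <- i
      }
    }
    close_region(start_i, prev, consensus)
  }
  regions <- do.call(rbind, reg_rows)
  consensus <- do.call(rbind, cons_rows)
  colnames(consensus) <- colnames(calls)
  regions$region_id <- sprintf("R%04d", seq_len(nrow(regions)))
  rownames(consensus) <- regions$region_id

  # arm assignment by region midpoint vs centromere
  cent <- vapply(regions$chromosome, function(ch) {
    if (!is.null(centromeres)) {
      p <- centromeres$position[centromeres$chromosome == ch]
      if (length(p)) return(p[1])
    }
    rows <- annotation$chromosome == ch
    (min(annotation$start[rows]) + max(annotation$end[rows])) / 2
  }, numeric(1))
  regions$arm <- ifelse((regions$start + regions$end) / 2 < cent, "p", "q")
  regions <- regions[, c("region_id", "chromosome", "arm", "start", "end",
                         "n_probes")]

  recon <- consensus[probe_region, , drop = FALSE]
  err <- mean(recon != calls)
  structure(list(regions = regions, consensus = consensus,
                 probe_region = probe_region, reconstruction_error = err,
                 tolerance = tolerance),
            class = "cna_subregions")
}

#' @export
print.cna_subregions <- function(x, ...) {
  cat("Chromosomal subregions:", nrow(x$regions), "regions from",
      length(x$probe_region), "probes (tolerance", x$tolerance, ")\n")
  cat(sprintf("Reconstruction error: %.4g\n", x$reconstruction_error))
  invisible(x)
}

#' Per-sample carrier status of a region
#'
#' Loss carriers have call <= -1; gain carriers have call >= +1
#' (amplification counts as gain).
#'
#' @param calls Per-sample integer calls of the region (a row of the
#'   consensus matrix).
#' @param type `"gain"` or `"loss"`.
#' @return Logical vector of carrier flags.
#' @export
region_carrier_status <- function(calls, type = c("gain", "loss")) {
  type <- match.arg(type)
  if (type == "gain") calls >= 1L else calls <= -1L
}

#' Concatenate significant subregions into total regions
#'
#' Within one chromosome arm, flagged subregions are merged into "total"
#' regions: with `mode = "adjacent_within_arm"` maximal runs of consecutive
#' flagged subregions (in genomic order) form one region each; with
#' `mode = "within_arm"` all flagged subregions of an arm form a single
#' region.
#'
#' @param subregions A `cna_subregions` or its `regions` data.frame.
#' @param flags Logical vector aligned with the subregions.
#' @param mode Concatenation rule.
#' @return Data.frame of total regions: `label`, `chromosome`, `arm`,
#'   `start`, `end`, `n_subregions`, `members` (comma-separated region ids).
#' @export
concatenate_significant <- function(subregions,
                                    flags,
                                    mode = c("adjacent_within_arm",
                                             "within_arm")) {
  mode <- match.arg(mode)
  reg <- if (inherits(subregions, "cna_subregions")) subregions$regions
         else subregions
  if (length(flags) != nrow(reg))
    stop("flags must align with the subregions")
  out <- list()
  for (key in unique(paste(reg$chromosome, reg$arm))) {
    rows <- which(paste(reg$chromosome, reg$arm) == key & flags)
    if (!length(rows)) next
    groups <- if (mode == "within_arm") {
      list(rows)
    } else {
      # runs of consecutive subregion indices within the arm ordering
      arm_rows <- which(paste(reg$chromosome, reg$arm) == key)
      pos <- match(rows, arm_rows)
      split(rows, cumsum(c(1L, diff(pos) != 1L)))
    }
    for (g in groups) {
      out[[length(out) + 1L]] <- data.frame(
        label = sprintf("%s%s:%d-%d", reg$chromosome[g[1]], reg$arm[g[1]],
                        min(reg$start[g]), max(reg$end[g])),
        chromosome = reg$chromosome[g[1]], arm = reg$arm[g[1]],
        start = min(reg$start[g]), end = max(reg$end[g]),
        n_subregions = length(g),
        members = paste(reg$region_id[g], collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(label = character(), chromosome = character(),
                      arm = character(), start = numeric(), end = numeric(),
                      n_subregions = integer(), members = character(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res[order(res$chromosome, res$arm, res$start), , drop = FALSE]
}
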
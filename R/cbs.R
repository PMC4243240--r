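#' Parameters for circular binary segmentation
#'
#' @param alpha Significance level for accepting a split (permutation p of
#'   the maximal arc statistic), in (0, 1).
#' @param n_perm Number of within-segment permutations per tested split.
#' @param min_width Minimum segment width in probes (>= 2).
#' @param seed Integer seed for the permutation stream.
#' @return A list of class `cbs_params`.
#' @export
cbs_params <- function(alpha = 0.01, n_perm = 1000L, min_width = 2L,
                       seed = 1L) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (min_width < 2) stop("min_width must be >= 2")
  if (n_perm < 1) stop("n_perm must be >= 1")
  structure(list(alpha = alpha, n_perm = as.integer(n_perm),
                 min_width = as.integer(min_width), seed = as.integer(seed)),
            class = "cbs_params")
}

# Maximal circular-arc statistic of a numeric segment: the two-sample t-like
# statistic between the arc (i, j] and its complement, maximised over all
# arcs respecting min_width. Exposed for oracle tests.
max_arc_statistic <- function(x, min_width = 2L) {
  r <- cpp_max_arc(as.numeric(x), as.integer(min_width))
  list(stat = r[1], i = as.integer(r[2]), j = as.integer(r[3]))
}

# Recursive CBS on one chromosome; returns sorted breakpoint positions
# (index of the last probe of each segment but the final one).
cbs_chromosome <- function(x, params) {
  breaks <- integer(0)
  recurse <- function(lo, hi) {
    len <- hi - lo + 1L
    if (len < 2L * params$min_width) return(invisible(NULL))
    seg <- x[lo:hi]
    r <- max_arc_statistic(seg, params$min_width)
    if (r$stat <= 0) return(invisible(NULL))
    perm <- matrix(0, len, params$n_perm)
    for (b in seq_len(params$n_perm)) perm[, b] <- seg[sample.int(len)]
    pstats <- cpp_perm_max(perm, params$min_width)
    p <- (1 + sum(pstats >= r$stat)) / (params$n_perm + 1)
    if (p >= params$alpha) return(invisible(NULL))
    i <- r$i; j <- r$j  # arc (i, j], 1-based elements i+1..j
    if (i > 0L) breaks <<- c(breaks, lo + i - 1L)
    if (j < len) breaks <<- c(breaks, lo + j - 1L)
    if (i > 0L) recurse(lo, lo + i - 1L)
    recurse(lo + i, lo + j - 1L)
    if (j < len) recurse(lo + j, hi)
    invisible(NULL)
  }
  recurse(1L, length(x))
  sort(unique(breaks))
}

#' Segment a copy-number profile by circular binary segmentation
#'
#' Recursively finds, within each chromosome, the circular arc maximising a
#' two-sample t-like statistic between the arc and its complement, accepts
#' the split if its within-segment permutation p-value is below `alpha`, and
#' recurses into the resulting pieces. Segment means are arithmetic means of
#' member probes. Deterministic given `params$seed`.
#'
#' Chromosomes shorter than `2 * min_width` probes are returned as a single
#' segment.
#'
#' @param ratios Per-probe log2 ratios for one sample.
#' @param chromosome Per-probe chromosome labels (same length).
#' @param params A [cbs_params()].
#' @return A list of class `cna_seg`: `segments` (data.frame with
#'   `chromosome`, `start_probe`, `end_probe` -- global 1-based inclusive
#'   probe indices -- and `mean`, `n_probes`) and `segmean_per_probe`.
#' @export
segment_profile <- function(ratios, chromosome, params = cbs_params()) {
  if (length(ratios) != length(chromosome))
    stop("ratios and chromosome must have equal length")
  with_seed(params$seed, {
    segs <- list()
    for (ch in unique(chromosome)) {
      idx <- which(chromosome == ch)
      x <- ratios[idx]
      breaks <- if (length(x) >= 2L * params$min_width)
        cbs_chromosome(x, params) else integer(0)
      starts <- c(1L, breaks + 1L)
      ends <- c(breaks, length(x))
      for (s in seq_along(starts)) {
        rows <- starts[s]:ends[s]
        segs[[length(segs) + 1L]] <- data.frame(
          chromosome = ch,
          start_probe = idx[starts[s]], end_probe = idx[ends[s]],
          mean = mean(x[rows]), n_probes = length(rows),
          stringsAsFactors = FALSE)
      }
    }
    segments <- do.call(rbind, segs)
    spp <- rep(segments$mean, segments$n_probes)
    structure(list(segments = segments, segmean_per_probe = spp),
              class = "cna_seg")
  })
}

#' @export
print.cna_seg <- function(x, ...) {
  cat("CBS segmentation:", nrow(x$segments), "segments over",
      length(x$segmean_per_probe), "probes\n")
  print(utils::head(x$segments, 10))
  if (nrow(x$segments) > 10) cat("...\n")
  invisible(x)
}
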
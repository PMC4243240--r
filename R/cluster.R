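#' Unsupervised clustering of samples on ordinal copy-number calls
#'
#' Agglomerative hierarchical clustering of samples with the distance
#' between two samples defined as the mean absolute difference of their
#' ordinal calls (-1, 0, 1, 2) across regions, and Ward linkage
#' (`hclust` method `ward.D2`); the dendrogram is cut at `k` clusters.
#' Deterministic for a given input.
#'
#' @param calls Region (or probe) x sample integer call matrix.
#' @param k Number of clusters (>= 2, <= number of samples).
#' @return List with `labels` (named cluster assignment), `hclust` (the
#'   tree) and `sizes`.
#' @export
cluster_samples <- function(calls, k = 2L) {
  n <- ncol(calls)
  if (k < 2) stop("k must be >= 2")
  if (k > n) stop("k exceeds the number of samples")
  d <- stats::dist(t(calls), method = "manhattan") / nrow(calls)
  hc <- hclust(d, method = "ward.D2")
  labels <- cutree(hc, k = k)
  list(labels = labels, hclust = hc, sizes = as.integer(table(labels)))
}

#' Cluster enrichment for a binary flag
#'
#' Pearson chi-square test (no continuity correction) on the k x 2 table of
#' cluster membership against a binary flag, e.g. MSI status.
#'
#' @param labels Cluster labels.
#' @param flags Logical flag per sample, aligned with `labels`.
#' @return List with the contingency `table`, `statistic` and `p`.
#' @export
cluster_enrichment <- function(labels, flags) {
  if (length(labels) != length(flags))
    stop("labels and flags must have equal length")
  tab <- table(cluster = labels, flag = flags)
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  list(table = tab, statistic = unname(ct$statistic), p = ct$p.value)
}
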
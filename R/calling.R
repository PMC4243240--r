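#' Four-state aberration calling by a Gaussian mixture on segment means
#'
#' Fits, per sample, a four-component one-dimensional Gaussian mixture
#' (states loss / normal / gain / amplification) to the purity-corrected
#' segment means, weighted by segment probe counts. The components share one
#' variance and start at means (-0.45, 0, 0.3, 0.9). To keep the states
#' identifiable in a per-sample fit, each component mean is confined to a
#' state window (loss <= -0.15, normal in [-0.1, 0.1], gain in [0.15, 0.75],
#' amplification >= 0.8, log2 units); the windows are disjoint and
#' increasing, which enforces the ordered-means constraint, and the
#' amplification component is unconstrained upward. EM runs to a
#' log-likelihood tolerance of 1e-8 or 500 iterations. A component whose
#' responsibility mass vanishes keeps its initial mean and a zero mixing
#' weight (its state remains addressable with zero posterior).
#'
#' A segment is called the posterior-argmax state when that posterior is at
#' least 0.5, otherwise normal. Any amplification-called segment whose
#' genomic span exceeds `amp_max_span` (3 Mb by default, boundary inclusive:
#' spans of exactly 3 Mb remain amplifications) is downgraded to gain.
#'
#' @param seg A `cna_seg` from [segment_profile()] (segment means should be
#'   purity-corrected first).
#' @param annotation Probe annotation data.frame (`chromosome`, `start`,
#'   `end`), used to measure segment genomic spans; if `NULL` the 3 Mb rule
#'   is skipped.
#' @param init_means Initial component means.
#' @param mean_windows 4 x 2 matrix of per-state mean bounds (rows loss,
#'   normal, gain, amplification).
#' @param amp_max_span Maximum genomic span (bp) of an amplification.
#' @param tol EM log-likelihood convergence tolerance.
#' @param max_iter Maximum EM iterations.
#' @return A list of class `cna_calls_sample`: `segments` (with `call` in
#'   {-1, 0, 1, 2} and `posterior` columns `p_loss`, `p_normal`, `p_gain`,
#'   `p_amp`), `calls_per_probe`, `posterior_per_probe` (probe x 4 matrix),
#'   `mixture` (fitted means, sd, weights, loglik, iterations).
#' @export
call_profile <- function(seg, annotation = NULL,
                         init_means = c(-0.45, 0, 0.3, 0.9),
                         mean_windows = rbind(c(-Inf, -0.15), c(-0.1, 0.1),
                                              c(0.15, 0.75), c(0.8, Inf)),
                         amp_max_span = 3e6, tol = 1e-8, max_iter = 500L) {
  stopifnot(inherits(seg, "cna_seg"), length(init_means) == 4)
  segments <- seg$segments
  x <- segments$mean
  w <- segments$n_probes
  fit <- .em_mixture(x, w, init_means, mean_windows, tol, max_iter)
  post <- fit$posterior  # nseg x 4
  colnames(post) <- c("p_loss", "p_normal", "p_gain", "p_amp")
  states <- c(-1L, 0L, 1L, 2L)
  amax <- max.col(post, ties.method = "first")
  call <- ifelse(post[cbind(seq_along(amax), amax)] >= 0.5, states[amax], 0L)

  if (!is.null(annotation)) {
    span <- annotation$end[segments$end_probe] -
      annotation$start[segments$start_probe]
    call[call == 2L & span > amp_max_span] <- 1L
  }
  segments$call <- call
  segments <- cbind(segments, as.data.frame(post))
  structure(list(
    segments = segments,
    calls_per_probe = rep(call, w),
    posterior_per_probe = post[rep(seq_len(nrow(post)), w), , drop = FALSE],
    mixture = fit[c("means", "sd", "weights", "loglik", "iterations")]),
    class = "cna_calls_sample")
}

# Weighted EM for a 4-component shared-variance univariate Gaussian mixture.
# x: observations (segment means), w: non-negative weights (probe counts).
# Component means are clamped to disjoint per-state windows so a per-sample
# fit cannot relabel states; components whose responsibility mass is
# negligible are frozen at their current mean with mixing weight ~0 rather
# than collapsing onto the data.
.em_mixture <- function(x, w, init_means, mean_windows, tol = 1e-8,
                        max_iter = 500L) {
  K <- length(init_means)
  mu <- as.numeric(init_means)
  W <- sum(w)
  sigma2 <- max(1e-6, sum(w * (x - mu[apply(abs(outer(x, mu, "-")), 1,
                                            which.min)])^2) / W)
  pi_k <- rep(1 / K, K)
  loglik <- -Inf
  it <- 0L
  repeat {
    it <- it + 1L
    dens <- vapply(seq_len(K), function(k)
      pi_k[k] * dnorm(x, mu[k], sqrt(sigma2)), numeric(length(x)))
    dens <- matrix(dens, nrow = length(x))
    tot <- rowSums(dens)
    tot[tot <= 0] <- .Machine$double.xmin
    post <- dens / tot
    new_ll <- sum(w * log(tot))
    resp <- colSums(w * post)
    active <- resp > 1e-6 * W
    pi_k <- resp / W
    mu_new <- mu
    mu_new[active] <- (colSums(w * post * x)[active]) / resp[active]
    # per-state windows (disjoint, increasing: ordered means by construction)
    mu <- pmin(pmax(mu_new, mean_windows[, 1]), mean_windows[, 2])
    ss <- sum(w * post * (outer(x, mu, "-")^2))
    sigma2 <- max(ss / W, 1e-8)
    if (is.finite(loglik) && abs(new_ll - loglik) < tol) { loglik <- new_ll; break }
    loglik <- new_ll
    if (it >= max_iter) break
  }
  if (any(!active))
    message("call_profile: ", sum(!active),
            " mixture component(s) empty, kept at initial mean with zero weight")
  list(posterior = post, means = mu, sd = sqrt(sigma2), weights = pi_k,
       loglik = loglik, iterations = it)
}

#' @export
print.cna_calls_sample <- function(x, ...) {
  tab <- table(factor(x$calls_per_probe, levels = c(-1, 0, 1, 2),
                      labels = c("loss", "normal", "gain", "amp")))
  cat("Called profile:", nrow(x$segments), "segments;",
      "probe calls:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  cat(sprintf("Mixture means: %s; sd %.3f\n",
              paste(sprintf("%.3f", x$mixture$means), collapse = ", "),
              x$mixture$sd))
  invisible(x)
}
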
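#' Background-corrected, median-normalised log2 ratio profile
#'
#' Subtracts local background from tumour and reference intensities, forms
#' `log2((T-B)/(R-B))` per probe and recentres so the median of the profile
#' is exactly zero. Probes whose background-corrected intensity is
#' non-positive are floored at `epsilon` and flagged.
#'
#' @param tumour,reference Non-negative per-probe intensities, equal length.
#' @param background Per-probe local background (scalar or vector);
#'   default 0.
#' @param epsilon Floor applied to non-positive corrected intensities.
#' @return Numeric log2-ratio vector with median 0; attribute `flagged`
#'   holds the indices of floored probes.
#' @export
compute_log2_profile <- function(tumour, reference, background = 0,
                                 epsilon = 1e-3) {
  if (length(tumour) != length(reference))
    stop("tumour and reference must have equal length")
  background <- rep_len(background, length(tumour))
  tc <- tumour - background
  rc <- reference - background
  flagged <- which(tc <= 0 | rc <= 0)
  tc <- pmax(tc, epsilon)
  rc <- pmax(rc, epsilon)
  r <- log2(tc / rc)
  r <- r - median(r)
  attr(r, "flagged") <- flagged
  r
}

#' Remove hybridisation waves by regression on a wave reference
#'
#' Per chromosome, the profile is regressed on the wave reference (the mean
#' profile of copy-number-normal samples) and the fitted component
#' `beta_hat * w` is subtracted, leaving residuals uncorrelated with the
#' wave. Chromosomes whose reference has (near-)zero variance are skipped
#' with a message.
#'
#' @param ratios Numeric vector (one sample) or probe x sample matrix of
#'   log2 ratios.
#' @param wave_reference Per-probe reference wave, same probe order.
#' @param chromosome Per-probe chromosome labels.
#' @return Dewaved ratios, same shape as the input.
#' @export
dewave <- function(ratios, wave_reference, chromosome) {
  vec <- is.null(dim(ratios))
  x <- if (vec) matrix(ratios, ncol = 1) else ratios
  if (length(wave_reference) != nrow(x))
    stop("wave_reference length must match the number of probes")
  if (length(chromosome) != nrow(x))
    stop("chromosome length must match the number of probes")
  for (ch in unique(chromosome)) {
    idx <- which(chromosome == ch)
    w <- wave_reference[idx]
    vw <- sum((w - mean(w))^2)
    if (vw <= 1e-12) {
      message("dewave: zero-variance wave reference on ", ch, ", skipped")
      next
    }
    wc <- w - mean(w)
    beta <- crossprod(wc, x[idx, , drop = FALSE]) / vw  # 1 x nsamp
    x[idx, ] <- x[idx, , drop = FALSE] - outer(w, as.numeric(beta))
  }
  if (vec) as.numeric(x) else x
}

#' Post-segmentation mode normalisation
#'
#' Estimates the mode of the probe-weighted distribution of segment means by
#' a Gaussian kernel density (Silverman's bandwidth) over per-probe segment
#' means, and subtracts it, so the dominant (assumed diploid) copy-number
#' state sits at log2 ratio 0. With a single distinct segment mean the shift
#' is that mean exactly.
#'
#' @param segments Segment data.frame as returned by [segment_profile()]
#'   (columns `mean`, `n_probes`).
#' @param ratios Optional per-probe log2 ratios to shift alongside.
#' @return List with `shift` (the subtracted mode), shifted `segments` and
#'   (if supplied) shifted `ratios`.
#' @export
mode_normalize <- function(segments, ratios = NULL) {
  m <- segments$mean
  w <- segments$n_probes
  per_probe <- rep(m, w)
  shift <- if (length(unique(m)) == 1L) {
    m[1]
  } else {
    d <- density(per_probe, bw = "nrd0")
    top <- which(d$y >= max(d$y) - 1e-12)
    # ties within tolerance: smallest |shift|
    d$x[top[which.min(abs(d$x[top]))]]
  }
  segments$mean <- segments$mean - shift
  out <- list(shift = shift, segments = segments)
  if (!is.null(ratios)) out$ratios <- ratios - shift
  out
}

#' Correct segment means for tumour-cell fraction
#'
#' The observed linear ratio of a specimen with tumour-cell fraction p and
#' tumour copy number c is `p*c/2 + (1-p)`; inverting on the log2 scale,
#' `corrected = log2(max((2^m - (1-p))/p, epsilon))`. With p = 1 the means
#' are unchanged. Values falling below the floor are clipped at
#' `log2(epsilon)`.
#'
#' @param means Numeric segment means (log2 units).
#' @param purity Tumour-cell fraction in (0, 1].
#' @param epsilon Linear-scale clip floor (default `2^-10`).
#' @return Corrected means.
#' @export
purity_correct <- function(means, purity, epsilon = 2^-10) {
  if (length(purity) != 1 || is.na(purity) || purity <= 0 || purity > 1)
    stop("purity must be a single value in (0, 1]")
  lin <- (2^means - (1 - purity)) / purity
  clipped <- lin < epsilon
  if (any(clipped))
    message("purity_correct: ", sum(clipped), " segment mean(s) clipped at floor")
  log2(pmax(lin, epsilon))
}

#' Residual MAD of a segmented profile
#'
#' The median over probes of the absolute residual from the probe's segment
#' mean, unscaled (no normal-consistency factor). This is the per-profile
#' noise metric used for quality control.
#'
#' @param ratios Per-probe log2 ratios.
#' @param segmean Per-probe segment means (same length), e.g.
#'   `segmean_per_probe` from [segment_profile()].
#' @return Non-negative scalar.
#' @export
compute_mad <- function(ratios, segmean) {
  if (length(ratios) != length(segmean))
    stop("ratios and segmean must have equal length")
  median(abs(ratios - segmean))
}

#' Profile-level quality filter on MAD
#'
#' Profiles with MAD above the threshold are excluded; the boundary is
#' inclusive (MAD equal to the threshold is kept).
#'
#' @param mads Named numeric vector of per-profile MAD values.
#' @param threshold Exclusion threshold (default 0.4).
#' @return Data.frame with `sample_id`, `mad`, `qc_pass`.
#' @export
qc_filter <- function(mads, threshold = 0.4) {
  data.frame(sample_id = if (is.null(names(mads))) seq_along(mads) else names(mads),
             mad = as.numeric(mads),
             qc_pass = as.numeric(mads) <= threshold,
             stringsAsFactors = FALSE, row.names = NULL)
}
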
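#' Histogram of an intensity plane on [0, 1]
#'
#' Equal-width binning used by both global thresholding methods.  Values are
#' expected in [0, 1]; the value 1 falls in the last bin.
#'
#' @param plane numeric matrix or vector of intensities in [0, 1].
#' @param n_bins number of bins (default 256, the convention for data derived
#'   from 8-bit acquisitions).
#' @return integer vector of bin counts, length `n_bins`.
#' @keywords internal
intensity_histogram <- function(plane, n_bins = 256L) {
  v <- as.numeric(plane)
  if (length(v) == 0L) stop("plane is empty")
  if (anyNA(v)) stop("plane contains NA")
  if (min(v) < 0 || max(v) > 1) stop("intensities must lie in [0, 1]")
  idx <- pmin(floor(v * n_bins) + 1L, n_bins)
  tabulate(idx, nbins = n_bins)
}

#' Maximum-entropy (Kapur) global threshold
#'
#' Builds a `n_bins` equal-width histogram on [0, 1] and returns the threshold
#' maximizing the sum of the Shannon entropies of the background (bins at or
#' below the split) and foreground (bins above it) histogram halves.  The
#' threshold is reported as the upper edge of the selected bin; pixels
#' strictly greater than it are foreground.  Ties are resolved toward the
#' smallest qualifying threshold.  This is the raw threshold: callers apply
#' any correction factor and bounds afterwards via
#' [apply_correction_and_bounds()].
#'
#' @param plane numeric matrix/vector with values in [0, 1].
#' @param n_bins number of histogram bins (>= 2).
#' @return threshold in [0, 1].  A degenerate single-bin histogram (e.g. a
#'   constant plane) falls back to the plane mean, so a constant plane returns
#'   the constant and no pixel exceeds it.
#' @seealso [otsu_threshold()]
#' @export
kapur_threshold <- function(plane, n_bins = 256L) {
  n_bins <- as.integer(n_bins)
  if (n_bins < 2L) stop("n_bins must be >= 2")
  counts <- intensity_histogram(plane, n_bins)
  p <- counts / sum(counts)
  if (sum(p > 0) < 2L) return(mean(as.numeric(plane)))
  best_t <- NA_integer_
  best_obj <- -Inf
  cum <- cumsum(p)
  ent_term <- ifelse(p > 0, -p * log(p), 0)
  cum_ent <- cumsum(ent_term)
  total_ent <- cum_ent[n_bins]
  for (t in seq_len(n_bins - 1L)) {
    w0 <- cum[t]
    w1 <- 1 - w0
    if (w0 <= 0 || w1 <= 0) next
    # H(background) + H(foreground) for the normalized halves
    h0 <- cum_ent[t] / w0 + log(w0)
    h1 <- (total_ent - cum_ent[t]) / w1 + log(w1)
    obj <- h0 + h1
    if (obj > best_obj) {
      best_obj <- obj
      best_t <- t
    }
  }
  if (is.na(best_t)) return(mean(as.numeric(plane)))
  best_t / n_bins
}

#' Otsu two-class global threshold
#'
#' Same histogram scaffolding as [kapur_threshold()] but the objective is the
#' between-class variance of the two-class split, computed from bin midpoints.
#' Ties resolve to the smallest qualifying threshold.
#'
#' @inheritParams kapur_threshold
#' @return threshold in [0, 1]; degenerate histograms fall back to the plane
#'   mean (a plane of zeros returns 0).
#' @export
otsu_threshold <- function(plane, n_bins = 256L) {
  n_bins <- as.integer(n_bins)
  if (n_bins < 2L) stop("n_bins must be >= 2")
  counts <- intensity_histogram(plane, n_bins)
  p <- counts / sum(counts)
  if (sum(p > 0) < 2L) return(mean(as.numeric(plane)))
  mids <- (seq_len(n_bins) - 0.5) / n_bins
  w0 <- cumsum(p)
  mu0 <- cumsum(p * mids)
  mu_t <- mu0[n_bins]
  best_t <- NA_integer_
  best_obj <- -Inf
  for (t in seq_len(n_bins - 1L)) {
    if (w0[t] <= 0 || w0[t] >= 1) next
    m0 <- mu0[t] / w0[t]
    m1 <- (mu_t - mu0[t]) / (1 - w0[t])
    obj <- w0[t] * (1 - w0[t]) * (m0 - m1)^2
    if (obj > best_obj) {
      best_obj <- obj
      best_t <- t
    }
  }
  if (is.na(best_t)) return(mean(as.numeric(plane)))
  best_t / n_bins
}

#' Apply a threshold correction factor and clamp to bounds
#'
#' `clamp(raw * correction, lower, upper)` — the post-processing applied to
#' every raw global threshold (e.g. Kapur x 0.5 clamped to [0.3, 0.9] for
#' nuclei; Otsu x 1.0 for the cell-body foreground).
#'
#' @param raw raw threshold.
#' @param correction multiplicative correction factor (> 0).
#' @param lower,upper clamp bounds, `0 <= lower <= upper <= 1`.
#' @return corrected, clamped threshold.
#' @export
apply_correction_and_bounds <- function(raw, correction, lower, upper) {
  if (!is.finite(raw)) stop("raw threshold must be finite")
  if (correction <= 0) stop("correction must be > 0")
  if (lower < 0 || upper > 1 || lower > upper)
    stop("bounds must satisfy 0 <= lower <= upper <= 1")
  min(max(raw * correction, lower), upper)
}
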
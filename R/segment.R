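#' Parameters for primary-object (nucleus) identification
#'
#' Defaults reproduce the published image-cytometry settings for lymphocyte
#' nuclei at 20x: diameter gate 20-50 px, maximum-entropy (Kapur) global
#' threshold with correction factor 0.5 bounded to [0.3, 0.9], border objects
#' discarded, shape-based declumping with local maxima closer than 20 px
#' suppressed.
#'
#' @param min_diameter,max_diameter admissible equivalent circular diameters
#'   in pixels (`2 * sqrt(area / pi)`).
#' @param correction multiplicative correction applied to the raw Kapur
#'   threshold.
#' @param lower_bound,upper_bound clamp bounds on the corrected threshold.
#' @param discard_border drop nuclei touching any image edge?
#' @param maxima_suppression_distance distance-transform maxima closer than
#'   this (pixels, Euclidean) are merged during declumping.
#' @param smoothing_sigma Gaussian sigma (pixels) for smoothing the distance
#'   transform before maxima detection; `NULL` selects it automatically from
#'   the expected object size (`min_diameter / 3.5`).
#' @param n_bins histogram bins for thresholding.
#' @return object of class `primary_params`.
#' @export
primary_params <- function(min_diameter = 20, max_diameter = 50,
                           correction = 0.5, lower_bound = 0.3,
                           upper_bound = 0.9, discard_border = TRUE,
                           maxima_suppression_distance = 20,
                           smoothing_sigma = NULL, n_bins = 256L) {
  stopifnot(min_diameter > 0, min_diameter <= max_diameter,
            lower_bound >= 0, lower_bound <= upper_bound, upper_bound <= 1,
            correction > 0, maxima_suppression_distance >= 0)
  if (is.null(smoothing_sigma)) smoothing_sigma <- min_diameter / 3.5
  stopifnot(smoothing_sigma > 0)
  structure(list(min_diameter = min_diameter, max_diameter = max_diameter,
                 correction = correction, lower_bound = lower_bound,
                 upper_bound = upper_bound, discard_border = discard_border,
                 maxima_suppression_distance = maxima_suppression_distance,
                 smoothing_sigma = smoothing_sigma, n_bins = as.integer(n_bins)),
            class = "primary_params")
}

#' Parameters for secondary-object (cell) propagation
#'
#' Defaults match the published settings: Otsu global two-class threshold with
#' correction factor 1.0 and regularization factor 0.05.
#'
#' @param threshold_correction multiplicative correction on the raw Otsu
#'   threshold, in (0, 10].
#' @param regularization_lambda weight of the Euclidean step length in the
#'   propagation step cost `|dI| + lambda * ||step||`; larger values make the
#'   partition more distance-like (Voronoi in the limit), smaller values more
#'   intensity-driven.
#' @param n_bins histogram bins for Otsu.
#' @return object of class `propagation_params`.
#' @export
propagation_params <- function(threshold_correction = 1.0,
                               regularization_lambda = 0.05,
                               n_bins = 256L) {
  stopifnot(threshold_correction > 0, threshold_correction <= 10,
            regularization_lambda >= 0)
  structure(list(threshold_correction = threshold_correction,
                 regularization_lambda = regularization_lambda,
                 n_bins = as.integer(n_bins)),
            class = "propagation_params")
}

# regional maxima of `x` restricted to `mask`: pixels >= every 8-neighbor
# (neighbors outside the mask count as -Inf).  Plateaus are collapsed to one
# representative: the pixel with the largest value, ties to the
# topmost-leftmost in column-major order.
.regional_maxima <- function(x, mask) {
  nr <- nrow(x); nc <- ncol(x)
  xm <- matrix(-Inf, nr + 2L, nc + 2L)
  xm[2:(nr + 1L), 2:(nc + 1L)] <- ifelse(mask, x, -Inf)
  core <- xm[2:(nr + 1L), 2:(nc + 1L)]
  is_max <- is.finite(core)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0L && dj == 0L) next
    nb <- xm[(2:(nr + 1L)) + di, (2:(nc + 1L)) + dj]
    is_max <- is_max & (core >= nb)
  }
  if (!any(is_max)) return(NULL)
  plateau <- cc_label_cpp(is_max)
  idx <- which(plateau > 0L)
  groups <- split(idx, plateau[idx])
  best <- vapply(groups, function(pix)
    pix[which.max(x[pix])], numeric(1))  # first max in column-major order
  cbind(row = (best - 1) %% nrow(x) + 1, col = (best - 1) %/% nrow(x) + 1,
        value = x[best])
}

# merge maxima closer than `d`: process in decreasing value (ties: topmost-
# leftmost); a maximum within distance d of an already-kept one is dropped.
.suppress_maxima <- function(mx, d) {
  if (is.null(mx) || nrow(mx) <= 1L || d <= 0) return(mx)
  ord <- order(-mx[, "value"], mx[, "col"], mx[, "row"])
  mx <- mx[ord, , drop = FALSE]
  keep <- logical(nrow(mx))
  for (i in seq_len(nrow(mx))) {
    if (!any(keep)) { keep[i] <- TRUE; next }
    kept <- mx[keep, , drop = FALSE]
    dd <- sqrt((kept[, "row"] - mx[i, "row"])^2 +
               (kept[, "col"] - mx[i, "col"])^2)
    if (all(dd >= d)) keep[i] <- TRUE
  }
  mx[keep, , drop = FALSE]
}

#' Identify nuclei (primary objects) on the DAPI channel
#'
#' Thresholds the blue plane with the corrected, bounded Kapur threshold;
#' labels 8-connected foreground components; declumps touching nuclei by
#' shape (regional maxima of the Gaussian-smoothed Euclidean distance
#' transform, maxima closer than the suppression distance merged keeping the
#' larger distance value, then a marker-controlled watershed realized as
#' minimal total-variation flooding of the distance map); removes objects
#' whose equivalent circular diameter falls outside the admissible range and,
#' optionally, objects touching the image border.  Surviving nuclei are
#' relabeled 1..K in scan order.
#'
#' @param blue DAPI intensity plane, values in [0, 1].
#' @param params a [primary_params()] object.
#' @return list with `labels` (integer label matrix), `threshold` (corrected)
#'   and `raw_threshold`.
#' @export
identify_primary <- function(blue, params = primary_params()) {
  stopifnot(inherits(params, "primary_params"), is.matrix(blue))
  raw <- kapur_threshold(blue, params$n_bins)
  thr <- apply_correction_and_bounds(raw, params$correction,
                                     params$lower_bound, params$upper_bound)
  fg <- blue > thr
  if (!any(fg)) {
    return(list(labels = matrix(0L, nrow(blue), ncol(blue)),
                threshold = thr, raw_threshold = raw))
  }
  comp <- cc_label_cpp(fg)
  dist <- EBImage::distmap(matrix(as.numeric(fg), nrow(fg), ncol(fg)))
  ds <- EBImage::gblur(dist, sigma = params$smoothing_sigma)
  ds <- matrix(as.numeric(ds), nrow(fg), ncol(fg))

  # markers: regional maxima found over the whole foreground in one pass,
  # then suppressed within each connected component (the suppression radius
  # never reaches across components, so no component is starved of markers)
  mx <- .regional_maxima(ds, fg)
  mx_comp <- comp[cbind(mx[, "row"], mx[, "col"])]
  markers <- matrix(0L, nrow(fg), ncol(fg))
  next_lab <- 0L
  for (cid in sort(unique(comp[comp > 0L]))) {
    sub <- mx[mx_comp == cid, , drop = FALSE]
    if (nrow(sub) == 0L) {  # flat component: use its first pixel
      first <- which(comp == cid)[1L]
      sub <- cbind(row = (first - 1L) %% nrow(fg) + 1L,
                   col = (first - 1L) %/% nrow(fg) + 1L, value = 0)
    }
    sub <- .suppress_maxima(sub, params$maxima_suppression_distance)
    for (k in seq_len(nrow(sub))) {
      next_lab <- next_lab + 1L
      markers[sub[k, "row"], sub[k, "col"]] <- next_lab
    }
  }

  lab <- propagate_cpp(ds, markers, fg, 0)

  # size gate on equivalent circular diameter; border discard
  nlab <- max(lab)
  areas <- tabulate(lab[lab > 0L], nbins = nlab)
  diam <- 2 * sqrt(areas / pi)
  ok <- areas > 0L & diam >= params$min_diameter & diam <= params$max_diameter
  if (params$discard_border) {
    border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
    ok[border[border > 0L]] <- FALSE
  }
  keep <- which(ok)
  map <- integer(nlab + 1L)
  map[keep + 1L] <- seq_along(keep)
  relab <- matrix(map[lab + 1L], nrow(lab), ncol(lab))
  list(labels = relab, threshold = thr, raw_threshold = raw)
}

#' Grow cells (secondary objects) from nuclei by seeded propagation
#'
#' The green plane is thresholded with the corrected Otsu threshold to define
#' the cell-body foreground; every foreground pixel reachable from a nucleus
#' is assigned to the seed of minimal accumulated path cost, where an
#' 8-connected step costs `|dI| + lambda * ||step||` and ties are broken by
#' accumulated path length, then seed label.  Seed pixels always belong to
#' their own cell (a nucleus lying wholly in background yields a cell equal to
#' the nucleus).  Output labels equal seed labels.
#'
#' @param green cell-body/CD4 intensity plane in [0, 1].
#' @param seeds nucleus label matrix (e.g. from [identify_primary()]).
#' @param params a [propagation_params()] object.
#' @return list with `labels`, `threshold`, `raw_threshold`.
#' @export
identify_secondary_propagation <- function(green, seeds,
                                           params = propagation_params()) {
  stopifnot(inherits(params, "propagation_params"), is.matrix(green),
            is.matrix(seeds), all(dim(green) == dim(seeds)))
  raw <- otsu_threshold(green, params$n_bins)
  thr <- min(max(raw * params$threshold_correction, 0), 1)
  fg <- green > thr
  lab <- propagate_cpp(green, seeds, fg, params$regularization_lambda)
  list(labels = lab, threshold = thr, raw_threshold = raw)
}

#' Cytoplasm (tertiary object): cell minus nucleus
#'
#' Pixel-exact set difference per label: `cytoplasm(k) = cells(k) \ nuclei(k)`.
#'
#' @param cells,nuclei aligned label matrices sharing label identities.
#' @return cytoplasm label matrix.
#' @export
identify_tertiary <- function(cells, nuclei) {
  if (!all(dim(cells) == dim(nuclei))) stop("label maps differ in shape")
  cyt <- cells
  cyt[nuclei > 0L] <- 0L
  cyt
}

#' Full three-tier segmentation of one field
#'
#' Runs [identify_primary()], [identify_secondary_propagation()] and
#' [identify_tertiary()] and returns the three mutually consistent label maps.
#'
#' @param image a `multichannel_image` (see [as_multichannel_image()]).
#' @param primary a [primary_params()] object.
#' @param propagation a [propagation_params()] object.
#' @return object of class `segmentation_result`: list with `nuclei`, `cells`,
#'   `cytoplasm` label matrices and `thresholds` (raw + corrected, per
#'   channel).
#' @export
segment_field <- function(image, primary = primary_params(),
                          propagation = propagation_params()) {
  image <- as_multichannel_image(image)
  prim <- identify_primary(image$blue, primary)
  sec <- identify_secondary_propagation(image$green, prim$labels, propagation)
  cyt <- identify_tertiary(sec$labels, prim$labels)
  structure(list(nuclei = prim$labels, cells = sec$labels, cytoplasm = cyt,
                 thresholds = list(
                   nuclei_raw = prim$raw_threshold, nuclei = prim$threshold,
                   cells_raw = sec$raw_threshold, cells = sec$threshold)),
            class = "segmentation_result")
}
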
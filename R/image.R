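#' Multi-channel fluorescence image
#'
#' One microscopy field as three co-registered intensity planes on a common
#' [0, 1] scale: red (FOXP3), green (CD4 / autofluorescence), blue (DAPI).
#' Pixel coordinates are 0-based conceptually but stored as ordinary R
#' matrices (row = y, column = x).
#'
#' @param red,green,blue numeric matrices of identical dimensions with values
#'   in [0, 1].
#' @return object of class `multichannel_image`.
#' @export
multichannel_image <- function(red, green, blue) {
  planes <- list(red = red, green = green, blue = blue)
  for (nm in names(planes)) {
    p <- planes[[nm]]
    if (!is.matrix(p) || !is.numeric(p))
      stop(sprintf("%s plane must be a numeric matrix", nm))
    if (anyNA(p) || min(p) < 0 || max(p) > 1)
      stop(sprintf("%s plane must lie in [0, 1] without NA", nm))
  }
  if (!all(dim(red) == dim(green)) || !all(dim(red) == dim(blue)))
    stop("planes must share dimensions")
  structure(planes, class = "multichannel_image")
}

#' Coerce to a multichannel_image
#'
#' Accepts an existing `multichannel_image`, a named list with `red`, `green`,
#' `blue` matrices, or a 3-slice array (rows x cols x RGB).
#'
#' @param x object to coerce.
#' @return a `multichannel_image`.
#' @export
as_multichannel_image <- function(x) {
  if (inherits(x, "multichannel_image")) return(x)
  if (is.array(x) && length(dim(x)) == 3L && dim(x)[3] == 3L)
    return(multichannel_image(x[, , 1], x[, , 2], x[, , 3]))
  if (is.list(x) && all(c("red", "green", "blue") %in% names(x)))
    return(multichannel_image(x$red, x$green, x$blue))
  stop("cannot interpret input as a multichannel image")
}

#' @export
print.multichannel_image <- function(x, ...) {
  cat(sprintf("<multichannel_image> %d x %d px (red/green/blue in [0,1])\n",
              nrow(x$red), ncol(x$red)))
  invisible(x)
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf(
    "<segmentation_result> %d nuclei | thresholds: DAPI %.4f (raw %.4f), green %.4f (raw %.4f)\n",
    length(setdiff(unique(as.integer(x$nuclei)), 0L)),
    x$thresholds$nuclei, x$thresholds$nuclei_raw,
    x$thresholds$cells, x$thresholds$cells_raw))
  invisible(x)
}

# evaluate an RNG-consuming expression under a fixed seed, restoring the
# caller's RNG state afterwards; seed = NULL uses the current stream
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  } else {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
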
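#' Read one field from TIFF
#'
#' Accepts a single RGB TIFF or three single-channel grayscale TIFFs (red,
#' green, blue order).  Integer TIFFs are normalized to [0, 1] by bit depth
#' (the `tiff` package already returns data on [0, 1] for 8- and 16-bit
#' files).
#'
#' @param path path to an RGB TIFF, or character vector of three paths to
#'   per-channel grayscale TIFFs.
#' @return a `multichannel_image`.
#' @export
read_field <- function(path) {
  if (length(path) == 3L) {
    planes <- lapply(path, function(p) {
      x <- tryCatch(tiff::readTIFF(p),
                    error = function(e) stop("cannot read TIFF: ", p))
      if (length(dim(x)) != 2L)
        stop("expected a single-channel grayscale TIFF: ", p)
      x
    })
    return(multichannel_image(planes[[1]], planes[[2]], planes[[3]]))
  }
  x <- tryCatch(tiff::readTIFF(path),
                error = function(e) stop("cannot read TIFF: ", path))
  if (length(dim(x)) != 3L || !dim(x)[3] %in% c(3L, 4L))
    stop("expected an RGB TIFF with 3 (or 4) channels: ", path)
  multichannel_image(x[, , 1], x[, , 2], x[, , 3])
}

#' Write a field as an RGB TIFF
#'
#' @param image a `multichannel_image`.
#' @param path output path.
#' @param bits bits per sample (8 or 16).
#' @return `path`, invisibly.
#' @export
write_field <- function(image, path, bits = 16L) {
  image <- as_multichannel_image(image)
  arr <- array(0, c(dim(image$red), 3L))
  arr[, , 1] <- image$red; arr[, , 2] <- image$green; arr[, , 3] <- image$blue
  tiff::writeTIFF(arr, path, bits.per.sample = as.integer(bits))
  invisible(path)
}

#' Write a label map as 16-bit single-channel TIFF
#'
#' Labels are stored as intensity `label / 65535`; [read_label_map()] inverts
#' the scaling.  Supports up to 65535 objects per field.
#'
#' @param labels integer label matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_label_map <- function(labels, path) {
  if (max(labels) > 65535L) stop("more than 65535 labels")
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_label_map
#' @export
read_label_map <- function(path) {
  x <- tiff::readTIFF(path)
  if (length(dim(x)) != 2L) stop("expected a single-channel label TIFF")
  matrix(as.integer(round(x * 65535)), nrow(x), ncol(x))
}

#' Pipeline configuration
#'
#' Bundles every tunable parameter of the pipeline; defaults equal the
#' published settings wherever one exists (Kapur correction 0.5, bounds
#' 0.3-0.9, diameters 20-50 px, maxima suppression 20 px, Otsu correction
#' 1.0, regularization 0.05, positivity multiplier 1.7, ratio offset 0.001).
#' Round-trips losslessly through YAML via [write_pipeline_config()] /
#' [read_pipeline_config()].
#'
#' @param primary a [primary_params()] object.
#' @param propagation a [propagation_params()] object.
#' @param k positivity-threshold multiplier.
#' @param pooling `"specimen"` (thresholds pooled over a patient's fields,
#'   the default) or `"field"`.
#' @param ratio_offset zero replacement in the ratio transform.
#' @param exact_limit largest group size for exact Wilcoxon.
#' @param seed integer seed recorded for provenance.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(primary = primary_params(),
                            propagation = propagation_params(),
                            k = 1.7, pooling = c("specimen", "field"),
                            ratio_offset = 0.001, exact_limit = 12L,
                            seed = NULL) {
  pooling <- match.arg(pooling)
  stopifnot(k > 0, ratio_offset > 0)
  structure(list(primary = primary, propagation = propagation, k = k,
                 pooling = pooling, ratio_offset = ratio_offset,
                 exact_limit = as.integer(exact_limit), seed = seed),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  plain <- list(
    primary = unclass(config$primary),
    propagation = unclass(config$propagation),
    k = config$k, pooling = config$pooling,
    ratio_offset = config$ratio_offset,
    exact_limit = config$exact_limit, seed = config$seed)
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  pipeline_config(
    primary = do.call(primary_params, y$primary[setdiff(names(y$primary),
                                                        character(0))]),
    propagation = do.call(propagation_params, y$propagation),
    k = y$k, pooling = y$pooling, ratio_offset = y$ratio_offset,
    exact_limit = y$exact_limit, seed = y$seed)
}

#' Write/read a cohort table as CSV
#'
#' Column layout: `patient_id, arm, age_group, gender, race, tobacco_alcohol,
#' t_stage, grade, pct_nfoxp3, pct_cfoxp3` (plus any derived columns).
#'
#' @param cohort cohort data frame.
#' @param path CSV path.
#' @return `path` / the cohort data frame.
#' @export
write_cohort_csv <- function(cohort, path) {
  write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  d$arm <- factor(d$arm, levels = c("control", "case"))
  for (cv in intersect(c("age_group", "gender", "race", "tobacco_alcohol",
                         "t_stage", "grade"), names(d)))
    d[[cv]] <- factor(d[[cv]])
  d
}
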
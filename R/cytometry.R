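#' Per-cell compartment mean intensities
#'
#' For every segmented cell, the arithmetic mean of the red (FOXP3) and green
#' (CD4) planes over the nucleus, the cytoplasm, and the whole cell
#' (nucleus + cytoplasm).  Cytoplasm means are `NA` when the cytoplasm is
#' empty (the cell propagated no further than its nucleus); such cells are
#' flagged downstream rather than dropped.
#'
#' @param image a `multichannel_image`.
#' @param seg a `segmentation_result` from [segment_field()] (or any list
#'   with aligned `nuclei`, `cells`, `cytoplasm` label matrices).
#' @return data frame with one row per cell: `cell_id`, `nucleus_mean_red`,
#'   `cytoplasm_mean_red`, `nucleus_mean_green`, `cytoplasm_mean_green`,
#'   `cell_mean_green`, `nucleus_area`, `cytoplasm_area`.
#' @export
measure_cells <- function(image, seg) {
  image <- as_multichannel_image(image)
  if (!all(dim(image$red) == dim(seg$nuclei)))
    stop("segmentation not aligned to image grid")
  cell_ids <- sort(setdiff(unique(as.integer(seg$cells)), 0L))
  nuc_ids <- sort(setdiff(unique(as.integer(seg$nuclei)), 0L))
  if (!all(cell_ids %in% nuc_ids))
    stop("cell label(s) without a matching nucleus: broken segmentation")
  if (length(cell_ids) == 0L) {
    return(data.frame(cell_id = integer(0), nucleus_mean_red = numeric(0),
                      cytoplasm_mean_red = numeric(0),
                      nucleus_mean_green = numeric(0),
                      cytoplasm_mean_green = numeric(0),
                      cell_mean_green = numeric(0), nucleus_area = integer(0),
                      cytoplasm_area = integer(0)))
  }
  comp_stats <- function(lab, plane) {
    v <- as.integer(lab)
    keep <- v > 0L
    sums <- rowsum(as.numeric(plane)[keep], v[keep])
    cnts <- rowsum(rep(1, sum(keep)), v[keep])
    list(ids = as.integer(rownames(sums)), sum = as.numeric(sums),
         n = as.numeric(cnts))
  }
  pick <- function(st, ids) {
    s <- setNames(rep(0, length(ids)), ids)
    n <- s
    m <- match(st$ids, ids)
    ok <- !is.na(m)
    s[m[ok]] <- st$sum[ok]
    n[m[ok]] <- st$n[ok]
    list(sum = s, n = n)
  }
  nr <- pick(comp_stats(seg$nuclei, image$red), cell_ids)
  ng <- pick(comp_stats(seg$nuclei, image$green), cell_ids)
  cr <- pick(comp_stats(seg$cytoplasm, image$red), cell_ids)
  cg <- pick(comp_stats(seg$cytoplasm, image$green), cell_ids)
  safe_mean <- function(s, n) ifelse(n > 0, s / n, NA_real_)
  data.frame(
    cell_id = cell_ids,
    nucleus_mean_red = safe_mean(nr$sum, nr$n),
    cytoplasm_mean_red = safe_mean(cr$sum, cr$n),
    nucleus_mean_green = safe_mean(ng$sum, ng$n),
    cytoplasm_mean_green = safe_mean(cg$sum, cg$n),
    cell_mean_green = (ng$sum + cg$sum) / (ng$n + cg$n),
    nucleus_area = as.integer(nr$n),
    cytoplasm_area = as.integer(cr$n))
}

#' Empirical positivity threshold: median + k x (2 x Q3 - median)
#'
#' The spread measure is the nonstandard `2 x Q3 - median` (a robust spread
#' estimate assuming symmetric dispersion around the median); the threshold
#' is `median + k * (2 * Q3 - median)` with default multiplier `k = 1.7`.
#' Quantiles use the linear-interpolation rule on order statistics (R's
#' default type 7), fixed because the nonstandard spread makes the result
#' sensitive to the quantile dialect.
#'
#' @param values numeric vector of MFIs (NAs dropped); must leave at least
#'   one value.
#' @param k threshold multiplier.
#' @return object of class `threshold_spec` with fields `median`, `q3`,
#'   `iqr_star`, `k`, `threshold`, `n`.
#' @export
positivity_threshold <- function(values, k = 1.7) {
  values <- values[!is.na(values)]
  if (length(values) == 0L) stop("no values to threshold")
  med <- unname(quantile(values, 0.5, type = 7))
  q3 <- unname(quantile(values, 0.75, type = 7))
  iqr_star <- 2 * q3 - med
  structure(list(median = med, q3 = q3, iqr_star = iqr_star, k = k,
                 threshold = med + k * iqr_star, n = length(values)),
            class = "threshold_spec")
}

#' @export
print.threshold_spec <- function(x, ...) {
  cat(sprintf(
    "<threshold_spec> median %.4g, Q3 %.4g, 2xQ3-median %.4g, k %.3g -> threshold %.4g (n = %d)\n",
    x$median, x$q3, x$iqr_star, x$k, x$threshold, x$n))
  invisible(x)
}

#' Positivity thresholds for the three measurement populations
#'
#' Computes one [positivity_threshold()] per population: whole-cell green
#' (CD4), nucleus red (nuclear FOXP3), cytoplasm red (cytoplasmic FOXP3).
#' With `pooling = "specimen"` (default) the populations pool all fields of
#' the specimen, mirroring the original processing of each patient's images
#' together; `pooling = "field"` is available for sensitivity analysis and
#' is applied by calling this per field.
#'
#' @param records per-cell measurement data frame(s) from [measure_cells()];
#'   a list of per-field data frames is pooled.
#' @param k threshold multiplier.
#' @return list with `cd4`, `foxp3_nuclear`, `foxp3_cytoplasmic`
#'   `threshold_spec`s.
#' @export
specimen_thresholds <- function(records, k = 1.7) {
  if (is.data.frame(records)) records <- list(records)
  pooled <- do.call(rbind, records)
  list(cd4 = positivity_threshold(pooled$cell_mean_green, k),
       foxp3_nuclear = positivity_threshold(pooled$nucleus_mean_red, k),
       foxp3_cytoplasmic = positivity_threshold(pooled$cytoplasm_mean_red, k))
}

#' Classify cells by CD4 positivity and FOXP3 compartment
#'
#' A cell is CD4+ iff its whole-cell mean green intensity is strictly greater
#' than the CD4 threshold ("superior to").  FOXP3 flags use the nucleus and
#' cytoplasm red means against their own thresholds; the pair of flags maps
#' to `negative`, `nuclear_only`, `cytoplasmic_only` or `dual`.  Cells with
#' an empty cytoplasm get a `FALSE` cytoplasmic flag and are marked for
#' audit.
#'
#' @param records data frame from [measure_cells()].
#' @param cd4_thr,foxp3_nuc_thr,foxp3_cyt_thr `threshold_spec`s, usually from
#'   [specimen_thresholds()] on the same specimen's records.
#' @return data frame: `cell_id`, `cd4_positive`, `foxp3_class` (factor),
#'   `audit_no_cytoplasm`.
#' @export
classify_cells <- function(records, cd4_thr, foxp3_nuc_thr, foxp3_cyt_thr) {
  for (t in list(cd4_thr, foxp3_nuc_thr, foxp3_cyt_thr))
    if (!inherits(t, "threshold_spec")) stop("thresholds must be threshold_spec")
  no_cyt <- records$cytoplasm_area == 0L
  nuc_pos <- records$nucleus_mean_red > foxp3_nuc_thr$threshold
  cyt_pos <- !no_cyt & !is.na(records$cytoplasm_mean_red) &
    records$cytoplasm_mean_red > foxp3_cyt_thr$threshold
  cls <- ifelse(nuc_pos & cyt_pos, "dual",
                ifelse(nuc_pos, "nuclear_only",
                       ifelse(cyt_pos, "cytoplasmic_only", "negative")))
  data.frame(
    cell_id = records$cell_id,
    cd4_positive = records$cell_mean_green > cd4_thr$threshold,
    foxp3_class = factor(cls, levels = c("negative", "nuclear_only",
                                         "cytoplasmic_only", "dual")),
    audit_no_cytoplasm = no_cyt)
}

#' Specimen-level summary percentages
#'
#' Pools cell classifications over all of one patient's fields and reports
#' percentages of CD4+ cells positive for FOXP3: in either compartment
#' (`pct_cd4foxp3`), only in the nucleus (`pct_nfoxp3`), only in the
#' cytoplasm (`pct_cfoxp3`).  Dual positives count toward `pct_cd4foxp3` and
#' `n_dual` but toward neither "only" percentage.  With no CD4+ cells the
#' percentages are `NA`.
#'
#' @param classifications data frame(s) from [classify_cells()]; a list of
#'   per-field data frames is pooled.
#' @param patient_id identifier carried into the summary row.
#' @return one-row data frame: `patient_id`, `n_cells`, `n_cd4`,
#'   `pct_cd4foxp3`, `pct_nfoxp3`, `pct_cfoxp3`, `n_dual`.
#' @export
summarize_specimen <- function(classifications, patient_id = NA_character_) {
  if (is.data.frame(classifications)) classifications <- list(classifications)
  if (length(classifications) < 1L) stop("at least one field required")
  pooled <- do.call(rbind, classifications)
  cd4 <- pooled[pooled$cd4_positive, , drop = FALSE]
  n_cd4 <- nrow(cd4)
  pct <- function(num) if (n_cd4 > 0) 100 * num / n_cd4 else NA_real_
  n_nuc <- sum(cd4$foxp3_class == "nuclear_only")
  n_cyt <- sum(cd4$foxp3_class == "cytoplasmic_only")
  n_dual <- sum(cd4$foxp3_class == "dual")
  data.frame(patient_id = patient_id, n_cells = nrow(pooled), n_cd4 = n_cd4,
             pct_cd4foxp3 = pct(n_nuc + n_cyt + n_dual),
             pct_nfoxp3 = pct(n_nuc), pct_cfoxp3 = pct(n_cyt),
             n_dual = n_dual, stringsAsFactors = FALSE)
}

#' Validate automatic against manual per-image counts
#'
#' Reproduces the validation protocol comparing computer counts with manual
#' counts over a set of images: per cell class and pooled, an ordinary
#' least-squares line `auto ~ manual` is fitted and its slope and R-squared
#' reported.  Slopes near 1 with high R-squared indicate agreement.
#'
#' @param auto_counts,manual_counts data frames or matrices of per-image
#'   counts with one column per cell class (same column order), >= 3 rows.
#' @return data frame with one row per class plus a `pooled` row: `class`,
#'   `slope`, `intercept`, `r_squared`, `n`.
#' @export
validate_against_manual <- function(auto_counts, manual_counts) {
  auto <- as.data.frame(auto_counts)
  manual <- as.data.frame(manual_counts)
  if (!all(dim(auto) == dim(manual)))
    stop("auto and manual counts must have identical shape")
  if (nrow(auto) < 3L) stop("need paired counts for at least 3 images")
  fit_one <- function(a, m, label) {
    f <- lm(a ~ m)
    ss_res <- sum(f$residuals^2)
    ss_tot <- sum((a - mean(a))^2)
    data.frame(class = label, slope = unname(coef(f)[2]),
               intercept = unname(coef(f)[1]),
               r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
               n = length(a), stringsAsFactors = FALSE)
  }
  rows <- lapply(seq_len(ncol(auto)), function(j)
    fit_one(auto[[j]], manual[[j]], colnames(auto)[j]))
  rows <- c(rows, list(fit_one(unlist(auto), unlist(manual), "pooled")))
  do.call(rbind, rows)
}
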
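#' Run the full image-to-biomarker pipeline
#'
#' Executes segment -> measure -> classify -> summarize for every specimen,
#' joins the specimen summaries to the cohort table on `patient_id`, derives
#' the offset log2 nuclear/cytoplasmic ratio, and runs the statistical layer
#' ([cohort_stats()]).  A manifest records every parameter affecting the
#' output plus the per-field thresholds actually chosen (the main audit
#' trail, since all positivity thresholds are data-driven).
#'
#' @param specimens named list (names = patient ids); each element is a list
#'   of fields, each a `multichannel_image` (or coercible via
#'   [as_multichannel_image()]).
#' @param cohort data frame with `patient_id`, `arm` and covariates; marker
#'   columns are taken from the images, any `pct_*` columns already present
#'   are replaced.
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; when given, per-cell measurements,
#'   specimen summaries, the merged cohort and the manifest are written
#'   (CSV/JSON).
#' @return list with `summaries` (per-specimen data frame), `cohort` (merged,
#'   with derived ratio columns), `stats` (from [cohort_stats()]; NULL when
#'   the cohort has fewer than 3 patients per arm), `cells` (per-cell records
#'   with patient/field ids), `manifest`.
#' @export
run_pipeline <- function(specimens, cohort = NULL,
                         config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"), length(specimens) >= 1L)
  if (is.null(names(specimens)) || any(names(specimens) == ""))
    stop("specimens must be a named list (names = patient ids)")
  all_cells <- list()
  summaries <- list()
  thresholds_log <- list()
  for (pid in names(specimens)) {
    fields <- specimens[[pid]]
    if (length(fields) < 1L) stop("specimen without fields: ", pid)
    recs <- list()
    for (fi in seq_along(fields)) {
      img <- tryCatch(
        as_multichannel_image(fields[[fi]]),
        error = function(e) stop("[input] ", pid, " field ", fi, ": ",
                                 conditionMessage(e)))
      seg <- tryCatch(
        segment_field(img, config$primary, config$propagation),
        error = function(e) stop("[segment] ", pid, " field ", fi, ": ",
                                 conditionMessage(e)))
      rec <- tryCatch(
        measure_cells(img, seg),
        error = function(e) stop("[measure] ", pid, " field ", fi, ": ",
                                 conditionMessage(e)))
      rec$patient_id <- pid
      rec$field_id <- fi
      recs[[fi]] <- rec
      thresholds_log[[paste(pid, fi, sep = "/")]] <- seg$thresholds
    }
    if (config$pooling == "specimen") {
      thr <- specimen_thresholds(recs, config$k)
      cls <- lapply(recs, classify_cells, cd4_thr = thr$cd4,
                    foxp3_nuc_thr = thr$foxp3_nuclear,
                    foxp3_cyt_thr = thr$foxp3_cytoplasmic)
    } else {
      cls <- lapply(recs, function(r) {
        thr <- specimen_thresholds(r, config$k)
        classify_cells(r, thr$cd4, thr$foxp3_nuclear, thr$foxp3_cytoplasmic)
      })
    }
    summaries[[pid]] <- summarize_specimen(cls, pid)
    all_cells[[pid]] <- do.call(rbind, recs)
  }
  summaries <- do.call(rbind, summaries)
  rownames(summaries) <- NULL
  cells <- do.call(rbind, all_cells)
  rownames(cells) <- NULL

  merged <- NULL
  stats_out <- NULL
  if (!is.null(cohort)) {
    keep <- setdiff(names(cohort),
                    c("pct_nfoxp3", "pct_cfoxp3", "pct_cd4foxp3", "ratio",
                      "log2_ratio"))
    merged <- merge(cohort[, keep, drop = FALSE],
                    summaries[, c("patient_id", "n_cells", "n_cd4",
                                  "pct_cd4foxp3", "pct_nfoxp3",
                                  "pct_cfoxp3", "n_dual")],
                    by = "patient_id")
    merged <- ratio_transform_cohort(merged, config$ratio_offset)
    arm_n <- table(merged$arm[!is.na(merged$pct_nfoxp3)])
    if (length(arm_n) == 2L && all(arm_n >= 3L))
      stats_out <- cohort_stats(merged)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("foxcyto")),
    config = list(primary = unclass(config$primary),
                  propagation = unclass(config$propagation),
                  k = config$k, pooling = config$pooling,
                  ratio_offset = config$ratio_offset,
                  exact_limit = config$exact_limit, seed = config$seed),
    n_specimens = length(specimens),
    fields_per_specimen = vapply(specimens, length, integer(1)),
    thresholds = thresholds_log)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(cells, file.path(out_dir, "cell_measurements.csv"),
              row.names = FALSE)
    write.csv(summaries, file.path(out_dir, "specimen_summaries.csv"),
              row.names = FALSE)
    if (!is.null(merged))
      write_cohort_csv(merged, file.path(out_dir, "cohort_markers.csv"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  list(summaries = summaries, cohort = merged, stats = stats_out,
       cells = cells, manifest = manifest)
}
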
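#' Offset nuclear/cytoplasmic ratio and its log2
#'
#' Zero percentages are replaced by 0.001 (numerator and denominator alike)
#' before taking the ratio, so specimens with no positive cells in one
#' compartment remain usable; `(0, 0)` maps to ratio 1 and log2 0.  NA inputs
#' propagate to NA outputs.
#'
#' @param pct_n,pct_c percentages of CD4+ cells with nuclear-only /
#'   cytoplasmic-only FOXP3 (vectors recycle as usual).
#' @param offset value substituted for exact zeros (default 0.001).
#' @return data frame with columns `ratio`, `log2_ratio`.
#' @export
ratio_transform <- function(pct_n, pct_c, offset = 0.001) {
  if (any(pct_n < 0, na.rm = TRUE) || any(pct_c < 0, na.rm = TRUE))
    stop("percentages must be >= 0")
  n <- ifelse(pct_n == 0, offset, pct_n)
  c_ <- ifelse(pct_c == 0, offset, pct_c)
  ratio <- n / c_
  data.frame(ratio = ratio, log2_ratio = log2(ratio))
}

#' Append derived ratio columns to a cohort table
#'
#' @param cohort data frame with `pct_nfoxp3`, `pct_cfoxp3`.
#' @param offset zero replacement, as in [ratio_transform()].
#' @return the cohort with `ratio` and `log2_ratio` columns appended.
#' @export
ratio_transform_cohort <- function(cohort, offset = 0.001) {
  rt <- ratio_transform(cohort$pct_nfoxp3, cohort$pct_cfoxp3, offset)
  cohort$ratio <- rt$ratio
  cohort$log2_ratio <- rt$log2_ratio
  cohort
}

#' Wilcoxon rank-sum comparison of two groups
#'
#' Two-sided rank-sum test with midrank ties: exact when both samples have at
#' most `exact_limit` observations and the pooled data are tie-free,
#' otherwise the normal approximation with tie and continuity correction.
#' Completely tied data (all values identical) return p = 1.
#'
#' @param x,y numeric samples (NAs dropped).
#' @param exact_limit largest per-group size for the exact null distribution.
#' @return list with `statistic` (Mann-Whitney U for `x`), `p`, `method`.
#' @export
wilcoxon_rank_sum <- function(x, y, exact_limit = 12L) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0L || length(y) == 0L) stop("both samples must be non-empty")
  pooled <- c(x, y)
  if (length(unique(pooled)) == 1L) {
    return(list(statistic = length(x) * length(y) / 2, p = 1,
                method = "degenerate (all values tied)"))
  }
  ties <- anyDuplicated(pooled) > 0L
  use_exact <- !ties && length(x) <= exact_limit && length(y) <= exact_limit
  wt <- suppressWarnings(
    wilcox.test(x, y, exact = use_exact, correct = TRUE,
                alternative = "two.sided"))
  p <- wt$p.value
  if (!is.finite(p)) p <- 1  # zero-variance normal approximation
  list(statistic = unname(wt$statistic), p = p,
       method = if (use_exact) "exact" else "normal approximation")
}

#' Pearson and Spearman correlation with least-squares slope
#'
#' Product-moment and rank correlations with their t-based p-values, plus the
#' ordinary least-squares slope of `y ~ x` (e.g. the per-unit increase of
#' %nFOXP3 per %cFOXP3).
#'
#' @param x,y numeric vectors (pairwise-complete, n >= 3 after NA removal).
#' @return list: `pearson_r`, `r_squared`, `pearson_p`, `spearman_rho`,
#'   `spearman_p`, `slope`, `intercept`, `n`.
#' @export
correlations <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) {
    warning("constant input: correlations undefined")
    return(list(pearson_r = NA_real_, r_squared = NA_real_,
                pearson_p = NA_real_, spearman_rho = NA_real_,
                spearman_p = NA_real_, slope = NA_real_,
                intercept = NA_real_, n = length(x)))
  }
  pe <- cor.test(x, y, method = "pearson")
  sp <- suppressWarnings(cor.test(x, y, method = "spearman"))
  f <- lm(y ~ x)
  list(pearson_r = unname(pe$estimate),
       r_squared = unname(pe$estimate)^2,
       pearson_p = pe$p.value,
       spearman_rho = unname(sp$estimate),
       spearman_p = sp$p.value,
       slope = unname(coef(f)[2]), intercept = unname(coef(f)[1]),
       n = length(x))
}

#' Logistic regression of case status on a log2-scaled marker
#'
#' Maximum-likelihood fit of `arm ~ marker` (optionally plus one categorical
#' covariate).  When the marker is on the log2 scale the exponentiated
#' coefficient is the odds ratio per twofold increase.  Wald 95% CI and
#' p-value throughout.  Complete or quasi-complete separation is detected
#' (fitted probabilities collapsing to 0/1 or an exploding coefficient) and
#' flagged rather than silently reported.
#'
#' @param table data frame with an `arm` factor (levels control, case).
#' @param marker name of the marker column (already transformed, e.g.
#'   `log2_ratio`), or a numeric vector of length `nrow(table)`.
#' @param covariate optional name of one categorical covariate column.
#' @return object of class `logistic_fit`: list with `coefficient` (per log2
#'   unit), `se`, `odds_ratio`, `ci95`, `p`, `converged`, `separation`,
#'   `covariate_terms` (data frame or NULL), `n`.
#' @export
logistic_fit <- function(table, marker, covariate = NULL) {
  if (is.character(marker)) {
    mk <- table[[marker]]
    if (is.null(mk)) stop("marker column not found: ", marker)
  } else mk <- marker
  ok <- !is.na(mk) & !is.na(table$arm)
  if (!is.null(covariate)) ok <- ok & !is.na(table[[covariate]])
  d <- data.frame(y = as.integer(table$arm[ok] == "case"), marker = mk[ok])
  if (length(unique(d$y)) < 2L) stop("both arms must be represented")
  if (sd(d$marker) == 0) stop("marker is constant")
  if (!is.null(covariate)) d$covariate <- droplevels(factor(table[[covariate]][ok]))
  form <- if (is.null(covariate)) y ~ marker else y ~ marker + covariate
  fit <- suppressWarnings(glm(form, data = d, family = binomial()))
  cf <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  eps <- fitted(fit)
  separation <- any(eps > 1 - 1e-8) && any(eps < 1e-8) ||
    abs(cf[["marker"]]) > 15
  if (!fit$converged)
    stop("logistic fit did not converge after ", fit$iter, " iterations")
  z <- qnorm(0.975)
  beta <- cf[["marker"]]; sb <- se[["marker"]]
  cov_terms <- NULL
  if (!is.null(covariate)) {
    idx <- grep("^covariate", names(cf))
    cov_terms <- data.frame(
      term = sub("^covariate", "", names(cf)[idx]),
      odds_ratio = exp(cf[idx]),
      ci_lower = exp(cf[idx] - z * se[idx]),
      ci_upper = exp(cf[idx] + z * se[idx]),
      p = 2 * pnorm(-abs(cf[idx] / se[idx])),
      row.names = NULL, stringsAsFactors = FALSE)
  }
  structure(list(coefficient = beta, se = sb, odds_ratio = exp(beta),
                 ci95 = exp(c(beta - z * sb, beta + z * sb)),
                 p = 2 * pnorm(-abs(beta / sb)),
                 converged = fit$converged, separation = separation,
                 covariate_terms = cov_terms, n = nrow(d)),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf(
    "<logistic_fit> OR per twofold increase %.3g (95%% CI %.3g-%.3g), Wald p = %.3g, n = %d%s\n",
    x$odds_ratio, x$ci95[1], x$ci95[2], x$p, x$n,
    if (x$separation) " [separation suspected]" else ""))
  invisible(x)
}

#' Empirical ROC curve and AUC
#'
#' Step-function ROC over all distinct marker values: for each cutoff the
#' sensitivity is the fraction of cases strictly above it and one minus
#' specificity the fraction of controls strictly above it (cases are assumed
#' to have the higher marker).  The area under the curve is computed by the
#' trapezoid rule and equals the Mann-Whitney concordance (ties counted 1/2).
#'
#' @param marker numeric marker values.
#' @param arm factor/vector distinguishing cases from controls; `positive`
#'   names the case level.
#' @param positive the case label (default `"case"`).
#' @return object of class `roc_curve`: list with `points` (data frame
#'   `fpr`, `tpr` from (0,0) to (1,1)), `auc`, `n_cases`, `n_controls`.
#' @export
empirical_roc <- function(marker, arm, positive = "case") {
  ok <- !is.na(marker) & !is.na(arm)
  marker <- marker[ok]; arm <- arm[ok]
  is_case <- arm == positive
  if (!any(is_case) || all(is_case))
    stop("both arms must be non-empty")
  cases <- marker[is_case]
  controls <- marker[!is_case]
  cuts <- sort(unique(marker), decreasing = TRUE)
  tpr <- vapply(cuts, function(c) mean(cases > c), numeric(1))
  fpr <- vapply(cuts, function(c) mean(controls > c), numeric(1))
  pts <- rbind(data.frame(fpr = 0, tpr = 0), data.frame(fpr = fpr, tpr = tpr))
  pts <- pts[order(pts$fpr, pts$tpr), ]
  if (pts$fpr[nrow(pts)] != 1 || pts$tpr[nrow(pts)] != 1)
    pts <- rbind(pts, data.frame(fpr = 1, tpr = 1))
  auc <- sum(diff(pts$fpr) * (head(pts$tpr, -1) + pts$tpr[-1]) / 2)
  structure(list(points = pts, auc = auc, n_cases = length(cases),
                 n_controls = length(controls)),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> AUC %.4f (%d cases vs %d controls, %d points)\n",
              x$auc, x$n_cases, x$n_controls, nrow(x$points)))
  invisible(x)
}

# DeLong placement values: for each case, the mean concordance against all
# controls (and vice versa); their means equal the empirical AUC
.delong_placements <- function(cases, controls) {
  v10 <- vapply(cases, function(a)
    mean((a > controls) + 0.5 * (a == controls)), numeric(1))
  v01 <- vapply(controls, function(b)
    mean((cases > b) + 0.5 * (cases == b)), numeric(1))
  list(v10 = v10, v01 = v01)
}

#' Paired comparison of two markers' AUCs (DeLong)
#'
#' Nonparametric paired AUC-difference test using the DeLong covariance of
#' the placement values.  Both markers must be measured on the same patients
#' in the same order.  Identical markers (or any pair with degenerate
#' difference variance and zero difference) return p = 1.
#'
#' @param marker_a,marker_b numeric vectors, same patients, same order.
#' @param arm case/control labels; `positive` names the case level.
#' @param positive the case label.
#' @return list: `auc_a`, `auc_b`, `difference` (a minus b), `se`, `p`.
#' @export
compare_auc_paired <- function(marker_a, marker_b, arm, positive = "case") {
  ok <- !is.na(marker_a) & !is.na(marker_b) & !is.na(arm)
  marker_a <- marker_a[ok]; marker_b <- marker_b[ok]; arm <- arm[ok]
  is_case <- arm == positive
  if (!any(is_case) || all(is_case)) stop("both arms must be non-empty")
  pa <- .delong_placements(marker_a[is_case], marker_a[!is_case])
  pb <- .delong_placements(marker_b[is_case], marker_b[!is_case])
  auc_a <- mean(pa$v10)
  auc_b <- mean(pb$v10)
  m <- sum(is_case); n <- sum(!is_case)
  s10 <- cov(cbind(pa$v10, pb$v10))
  s01 <- cov(cbind(pa$v01, pb$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  diff <- auc_a - auc_b
  if (var_diff <= 0 || !is.finite(var_diff)) {
    p <- if (abs(diff) < 1e-12) 1 else 0
    return(list(auc_a = auc_a, auc_b = auc_b, difference = diff, se = 0,
                p = p))
  }
  z <- diff / sqrt(var_diff)
  list(auc_a = auc_a, auc_b = auc_b, difference = diff, se = sqrt(var_diff),
       p = 2 * pnorm(-abs(z)))
}

#' Univariate odds-ratio table for baseline covariates
#'
#' One univariate logistic fit of case status per covariate, against the
#' stated reference levels (first factor level = reference; defaults follow
#' the cohort generator: younger age, male, white non-Hispanic, neither
#' tobacco nor alcohol, T1, well differentiated).  Empty levels are dropped
#' with a warning; separation (e.g. a covariate identical to the arm) is
#' flagged with an infinite/huge OR rather than suppressed.
#'
#' @param table cohort data frame with `arm` and covariate factors.
#' @param covariates character vector of covariate column names.
#' @return data frame: `covariate`, `level`, `odds_ratio`, `ci_lower`,
#'   `ci_upper`, `p`, `separation`.
#' @export
covariate_table <- function(table,
                            covariates = c("age_group", "gender", "race",
                                           "tobacco_alcohol", "t_stage",
                                           "grade")) {
  rows <- list()
  z <- qnorm(0.975)
  for (cv in covariates) {
    f <- factor(table[[cv]])
    if (any(table(f) == 0L)) {
      warning("dropping empty level(s) of ", cv)
      f <- droplevels(f)
    }
    if (nlevels(f) < 2L) next
    d <- data.frame(y = as.integer(table$arm == "case"), x = f)
    d <- d[complete.cases(d), ]
    fit <- suppressWarnings(glm(y ~ x, data = d, family = binomial()))
    cf <- coef(fit)
    se <- sqrt(diag(vcov(fit)))
    idx <- grep("^x", names(cf))
    sep <- any(abs(cf[idx]) > 15)
    rows[[cv]] <- data.frame(
      covariate = cv, level = sub("^x", "", names(cf)[idx]),
      odds_ratio = exp(cf[idx]),
      ci_lower = exp(cf[idx] - z * se[idx]),
      ci_upper = exp(cf[idx] + z * se[idx]),
      p = 2 * pnorm(-abs(cf[idx] / se[idx])),
      separation = sep, row.names = NULL, stringsAsFactors = FALSE)
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Full marker statistics for a cohort
#'
#' Convenience layer running the whole statistical analysis on a cohort with
#' `pct_nfoxp3`, `pct_cfoxp3` (ratio columns appended if missing): Wilcoxon
#' case-control comparisons, within-arm correlations, empirical ROC/AUC per
#' marker, paired AUC comparisons, and logistic odds ratios per twofold
#' change (nuclear and ratio markers on +log2; the cytoplasmic marker is
#' reported per twofold decrease via -log2).
#'
#' @param cohort cohort data frame.
#' @return list with elements `wilcoxon`, `correlation_cases`,
#'   `correlation_controls`, `roc`, `auc_comparisons`, `logistic`.
#' @export
cohort_stats <- function(cohort) {
  if (is.null(cohort$log2_ratio)) cohort <- ratio_transform_cohort(cohort)
  off <- function(v) log2(ifelse(v == 0, 0.001, v))
  cohort$log2_nfoxp3 <- off(cohort$pct_nfoxp3)
  cohort$neg_log2_cfoxp3 <- -off(cohort$pct_cfoxp3)
  cases <- cohort[cohort$arm == "case", ]
  ctrls <- cohort[cohort$arm == "control", ]
  wil <- lapply(c(nfoxp3 = "pct_nfoxp3", cfoxp3 = "pct_cfoxp3",
                  log2_ratio = "log2_ratio"), function(cl)
    wilcoxon_rank_sum(cases[[cl]], ctrls[[cl]]))
  roc <- lapply(c(nfoxp3 = "pct_nfoxp3", cfoxp3 = "neg_log2_cfoxp3",
                  log2_ratio = "log2_ratio"), function(cl)
    empirical_roc(cohort[[cl]], cohort$arm))
  cmp <- list(
    ratio_vs_nuclear = compare_auc_paired(cohort$log2_ratio,
                                          cohort$pct_nfoxp3, cohort$arm),
    nuclear_vs_cytoplasmic = compare_auc_paired(cohort$pct_nfoxp3,
                                                cohort$neg_log2_cfoxp3,
                                                cohort$arm))
  logi <- list(
    nfoxp3 = logistic_fit(cohort, "log2_nfoxp3"),
    cfoxp3 = logistic_fit(cohort, "neg_log2_cfoxp3"),
    log2_ratio = logistic_fit(cohort, "log2_ratio"))
  list(wilcoxon = wil,
       correlation_cases = correlations(cases$pct_cfoxp3, cases$pct_nfoxp3),
       correlation_controls = correlations(ctrls$pct_cfoxp3,
                                           ctrls$pct_nfoxp3),
       roc = roc, auc_comparisons = cmp, logistic = logi)
}
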
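test_that("ratio transform applies the 0.001 offset to zeros only", {
  rt <- ratio_transform(c(4, 0, 0, NA), c(2, 5, 0, 1))
  expect_equal(rt$ratio, c(2, 0.001 / 5, 1, NA))
  expect_equal(rt$log2_ratio[1], 1)
  expect_equal(rt$log2_ratio[2], log2(0.0002))
  expect_equal(rt$log2_ratio[3], 0)
  expect_true(is.na(rt$log2_ratio[4]))
  # nonzero values are untouched (offset is not added everywhere)
  expect_equal(ratio_transform(0.5, 2)$ratio, 0.25)
  expect_error(ratio_transform(-1, 2), ">= 0")
})

test_that("rank-sum test: exact small-sample p-values and null identity", {
  r <- wilcoxon_rank_sum(c(1, 2), c(3, 4))
  expect_equal(r$p, 2 / 6, tolerance = 1e-12)
  expect_equal(r$method, "exact")
  same <- wilcoxon_rank_sum(c(1, 5, 9), c(9, 1, 5))
  expect_gte(same$p, 0.99)
  tied <- wilcoxon_rank_sum(rep(2, 5), rep(2, 7))
  expect_equal(tied$p, 1)
})

test_that("exact rank-sum p matches full enumeration for random samples", {
  set.seed(14)
  for (rep in 1:5) {
    x <- sample(seq_len(100), 8)
    y <- sample(setdiff(seq_len(100), x), 8)
    got <- wilcoxon_rank_sum(x, y)
    expect_equal(got$p, oracle_wilcoxon_exact(x, y), tolerance = 1e-12)
  }
})

test_that("correlations and slope match closed-form oracles", {
  x <- c(1, 2, 3, 4, 5)
  r1 <- correlations(x, 2 * x + 1)
  expect_equal(r1$pearson_r, 1)
  expect_equal(r1$r_squared, 1)
  expect_equal(r1$slope, 2)
  r2 <- correlations(x, -x)
  expect_equal(r2$pearson_r, -1)
  expect_equal(r2$spearman_rho, -1)
  set.seed(2)
  xs <- rnorm(20); ys <- 0.5 * xs + rnorm(20)
  got <- correlations(xs, ys)
  want <- oracle_ls(xs, ys)
  expect_equal(got$slope, want$slope, tolerance = 1e-10)
  expect_equal(got$r_squared, want$r_squared, tolerance = 1e-10)
  expect_equal(got$spearman_rho, cor(rank(xs), rank(ys)), tolerance = 1e-10)
  expect_warning(correlations(rep(1, 5), 1:5), "constant")
  expect_error(correlations(1:2, 1:2), "3")
})

test_that("logistic fit: symmetric data give OR exactly 1", {
  tab <- data.frame(arm = factor(c("control", "case", "control", "case"),
                                 levels = c("control", "case")),
                    marker = c(0, 0, 1, 1))
  fit <- logistic_fit(tab, "marker")
  expect_equal(fit$odds_ratio, 1, tolerance = 1e-8)
  expect_equal(fit$ci95[1] * fit$ci95[2], 1, tolerance = 1e-6)
})

test_that("logistic fit is near-null on independent marker at large n", {
  set.seed(10)
  n <- 10000L
  tab <- data.frame(arm = factor(sample(c("control", "case"), n, TRUE),
                                 levels = c("control", "case")),
                    marker = rnorm(n))
  fit <- logistic_fit(tab, "marker")
  expect_gt(fit$odds_ratio, 0.9)
  expect_lt(fit$odds_ratio, 1.1)
  expect_false(fit$separation)
})

test_that("complete separation is flagged, not silently reported", {
  tab <- data.frame(arm = factor(rep(c("control", "case"), each = 10),
                                 levels = c("control", "case")),
                    marker = c(rnorm(10, -5), rnorm(10, 5)))
  fit <- logistic_fit(tab, "marker")
  expect_true(fit$separation)
})

test_that("adjusted fits report covariate terms", {
  set.seed(77)
  n <- 400L
  cov <- factor(sample(c("a", "b"), n, TRUE))
  marker <- rnorm(n)
  arm <- factor(ifelse(runif(n) < plogis(0.8 * marker + 0.5 * (cov == "b")),
                       "case", "control"), levels = c("control", "case"))
  tab <- data.frame(arm = arm, marker = marker, grp = cov)
  fit <- logistic_fit(tab, "marker", covariate = "grp")
  expect_false(is.null(fit$covariate_terms))
  expect_equal(fit$covariate_terms$term, "b")
  expect_gt(fit$odds_ratio, exp(0.8) * 0.7)
  expect_lt(fit$odds_ratio, exp(0.8) * 1.4)
})

test_that("empirical ROC endpoints, monotonicity, and known AUCs", {
  arm <- factor(rep(c("control", "case"), each = 5),
                levels = c("control", "case"))
  perfect <- empirical_roc(c(1:5, 6:10), arm)
  expect_equal(perfect$auc, 1)
  flat <- empirical_roc(rep(3, 10), arm)
  expect_equal(flat$auc, 0.5)
  set.seed(6)
  m <- rnorm(10)
  rc <- empirical_roc(m, arm)
  expect_true(all(diff(rc$points$fpr) >= 0))
  expect_true(all(diff(rc$points$tpr) >= 0))
  expect_equal(rc$points[1, ], data.frame(fpr = 0, tpr = 0),
               ignore_attr = TRUE)
  expect_equal(as.numeric(rc$points[nrow(rc$points), ]), c(1, 1))
  expect_error(empirical_roc(m, rep("case", 10)), "both arms")
})

test_that("AUC agrees with pROC and is invariant to monotone transforms", {
  set.seed(19)
  arm <- factor(rep(c("control", "case"), c(30, 19)),
                levels = c("control", "case"))
  m <- c(rnorm(30), rnorm(19, 0.8))
  ours <- empirical_roc(m, arm)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(arm, m, levels = c("control", "case"),
                                        direction = "<", quiet = TRUE)))
  expect_equal(ours, ref, tolerance = 1e-12)
  expect_identical(empirical_roc(exp(m), arm)$auc, ours)
})

test_that("paired AUC comparison: identity, rank invariance, pROC match", {
  set.seed(23)
  arm <- factor(rep(c("control", "case"), c(30, 19)),
                levels = c("control", "case"))
  a <- c(rnorm(30), rnorm(19, 1))
  same <- compare_auc_paired(a, a, arm)
  expect_equal(same$difference, 0)
  expect_equal(same$p, 1)
  mono <- compare_auc_paired(a, qlogis(plogis(a)) * 3 + 2, arm)
  expect_equal(mono$difference, 0, tolerance = 1e-12)
  b <- c(rnorm(30), rnorm(19, 0.3))
  got <- compare_auc_paired(a, b, arm)
  ref <- pROC::roc.test(
    pROC::roc(arm, a, levels = c("control", "case"), direction = "<",
              quiet = TRUE),
    pROC::roc(arm, b, levels = c("control", "case"), direction = "<",
              quiet = TRUE),
    method = "delong", paired = TRUE)
  expect_equal(got$p, ref$p.value, tolerance = 1e-9)
  expect_equal(got$auc_a - got$auc_b,
               as.numeric(ref$estimate[1] - ref$estimate[2]),
               tolerance = 1e-12)
})

test_that("covariate odds-ratio table flags separation and finds nulls", {
  set.seed(55)
  n <- 2000L
  arm <- factor(sample(c("control", "case"), n, TRUE),
                levels = c("control", "case"))
  tab <- data.frame(
    arm = arm,
    mirror = factor(ifelse(arm == "case", "yes", "no")),  # identical to arm
    noise = factor(sample(c("lo", "hi"), n, TRUE)))
  out <- covariate_table(tab, c("mirror", "noise"))
  expect_true(out$separation[out$covariate == "mirror"])
  or_noise <- out$odds_ratio[out$covariate == "noise"]
  expect_gt(or_noise, 0.85)
  expect_lt(or_noise, 1.18)
})

test_that("planted covariate effects are recovered by the OR table", {
  set.seed(66)
  n <- 40000L  # se of the log-OR ~3%, so the 10% band is a >3-sigma check
  lev <- c("neither", "alcohol", "tobacco", "both")
  x <- factor(sample(lev, n, TRUE), levels = lev)
  eta <- -1 + log(5.8) * (x == "both")
  arm <- factor(ifelse(runif(n) < plogis(eta), "case", "control"),
                levels = c("control", "case"))
  out <- covariate_table(data.frame(arm = arm, tobacco_alcohol = x),
                         "tobacco_alcohol")
  or_both <- out$odds_ratio[out$level == "both"]
  expect_lt(abs(or_both - 5.8) / 5.8, 0.1)
})

test_that("cohort_stats runs the full layer on a default cohort", {
  co <- generate_cohort(cohort_sim_params(seed = 100L))
  st <- cohort_stats(co)
  expect_named(st, c("wilcoxon", "correlation_cases", "correlation_controls",
                     "roc", "auc_comparisons", "logistic"))
  expect_lt(st$wilcoxon$nfoxp3$p, 0.05)  # planted case-control separation
  expect_gt(st$roc$nfoxp3$auc, 0.5)
  expect_gt(st$correlation_cases$pearson_r, 0.5)  # planted correlation
  expect_gt(st$logistic$nfoxp3$odds_ratio, 1)
})
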
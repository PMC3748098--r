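make_seg <- function(nuclei, cells) {
  structure(list(nuclei = nuclei, cells = cells,
                 cytoplasm = identify_tertiary(cells, nuclei)),
            class = "segmentation_result")
}

test_that("compartment means are exact on constructed cases", {
  nuclei <- matrix(0L, 6, 6); cells <- matrix(0L, 6, 6)
  nuclei[2:3, 2:3] <- 1L
  cells[1:4, 1:4] <- 1L
  red <- matrix(0, 6, 6); green <- matrix(0, 6, 6); blue <- matrix(0, 6, 6)
  red[2:3, 2:3] <- 0.4                      # uniform nucleus
  red[1, 1] <- 0.0; red[1, 2] <- 1.0        # cytoplasm pixels
  green[1:4, 1:4] <- 0.25
  img <- multichannel_image(red, green, blue)
  rec <- measure_cells(img, make_seg(nuclei, cells))
  expect_equal(rec$nucleus_mean_red, 0.4)
  expect_equal(rec$nucleus_area, 4L)
  expect_equal(rec$cytoplasm_area, 12L)
  expect_equal(rec$cytoplasm_mean_red, 1.0 / 12)
  expect_equal(rec$cell_mean_green, 0.25)
  # two-pixel compartment valued 0 and 1 -> mean 0.5
  nuclei2 <- matrix(0L, 4, 4); cells2 <- matrix(0L, 4, 4)
  nuclei2[2, 2:3] <- 1L; cells2[2, 2:3] <- 1L
  red2 <- matrix(0, 4, 4); red2[2, 2] <- 0; red2[2, 3] <- 1
  img2 <- multichannel_image(red2, matrix(0.1, 4, 4), matrix(0, 4, 4))
  rec2 <- measure_cells(img2, make_seg(nuclei2, cells2))
  expect_equal(rec2$nucleus_mean_red, 0.5)
  expect_true(is.na(rec2$cytoplasm_mean_red))
  expect_equal(rec2$cytoplasm_area, 0L)
})

test_that("means equal brute-force per-pixel accumulation on random maps", {
  set.seed(11)
  for (rep in 1:3) {
    nr <- 16L; nc <- 16L
    nuclei <- matrix(0L, nr, nc); cells <- matrix(0L, nr, nc)
    # three random rectangular cells with inner nuclei
    anchors <- list(c(2, 2), c(2, 9), c(9, 4))
    for (k in 1:3) {
      a <- anchors[[k]]
      cells[a[1]:(a[1] + 5), a[2]:(a[2] + 5)] <- k
      nuclei[(a[1] + 1):(a[1] + 3), (a[2] + 1):(a[2] + 3)] <- k
    }
    red <- matrix(runif(nr * nc), nr, nc)
    green <- matrix(runif(nr * nc), nr, nc)
    img <- multichannel_image(red, green, matrix(0.5, nr, nc))
    rec <- measure_cells(img, make_seg(nuclei, cells))
    for (k in 1:3) {
      expect_equal(rec$nucleus_mean_red[k], mean(red[nuclei == k]))
      expect_equal(rec$cytoplasm_mean_red[k],
                   mean(red[cells == k & nuclei == 0L]))
      expect_equal(rec$cell_mean_green[k], mean(green[cells == k]))
    }
  }
})

test_that("a cell label without a nucleus is a broken invariant", {
  nuclei <- matrix(0L, 5, 5); cells <- matrix(0L, 5, 5)
  cells[2:4, 2:4] <- 1L  # no nucleus with label 1
  img <- multichannel_image(matrix(0, 5, 5), matrix(0, 5, 5),
                            matrix(0, 5, 5))
  expect_error(measure_cells(img, make_seg(nuclei, cells)), "nucleus")
})

test_that("positivity threshold follows median + k*(2*Q3 - median)", {
  # worked case: median 10, Q3 15 -> spread 20, threshold 10 + 1.7*20 = 44
  spec <- positivity_threshold(c(0, 5, 10, 15, 20), k = 1.7)
  expect_equal(spec$median, 10)
  expect_equal(spec$q3, 15)
  expect_equal(spec$iqr_star, 20)
  expect_equal(spec$threshold, 44)
  # identity holds to machine precision on random samples
  set.seed(20)
  for (i in 1:50) {
    v <- rexp(sample(5:200, 1))
    s <- positivity_threshold(v, k = 1.7)
    expect_identical(s$threshold, s$median + 1.7 * (2 * s$q3 - s$median))
    expect_identical(s$q3, unname(quantile(v, 0.75)))
  }
  expect_error(positivity_threshold(numeric(0)), "no values")
})

test_that("all-equal intensities yield a threshold no cell exceeds", {
  spec <- positivity_threshold(rep(0.3, 40))
  expect_equal(spec$threshold, 2.7 * 0.3)
  expect_equal(sum(rep(0.3, 40) > spec$threshold), 0L)
})

test_that("background-dominated mixtures recover the planted positive rate", {
  set.seed(33)
  v <- c(abs(rnorm(9500, 0.02, 0.01)), rnorm(500, 0.2, 0.02))
  spec <- positivity_threshold(v)
  frac_above <- mean(v > spec$threshold)
  expect_lt(abs(frac_above - 0.05), 0.01)
})

test_that("classification uses strict inequality and both red flags", {
  rec <- data.frame(
    cell_id = 1:5,
    nucleus_mean_red = c(0.60, 0.10, 0.10, 0.60, 0.10),
    cytoplasm_mean_red = c(0.10, 0.60, 0.10, 0.60, NA),
    nucleus_mean_green = 0.2, cytoplasm_mean_green = 0.2,
    cell_mean_green = c(0.80, 0.80, 0.50, 0.80, 0.80),
    nucleus_area = 10L, cytoplasm_area = c(8L, 8L, 8L, 8L, 0L))
  thr <- function(t) structure(list(threshold = t), class = "threshold_spec")
  cls <- classify_cells(rec, thr(0.5), thr(0.5), thr(0.5))
  expect_equal(as.character(cls$foxp3_class),
               c("nuclear_only", "cytoplasmic_only", "negative", "dual",
                 "negative"))
  # cell 3: cell_mean_green == threshold exactly -> negative ("superior to")
  expect_identical(cls$cd4_positive, c(TRUE, TRUE, FALSE, TRUE, TRUE))
  expect_identical(cls$audit_no_cytoplasm, c(rep(FALSE, 4), TRUE))
})

test_that("specimen summaries count classes with the CD4+ denominator", {
  cls <- data.frame(
    cell_id = 1:120,
    cd4_positive = c(rep(TRUE, 100), rep(FALSE, 20)),
    foxp3_class = factor(
      c(rep("nuclear_only", 20), rep("cytoplasmic_only", 10),
        rep("negative", 70), rep("nuclear_only", 20)),
      levels = c("negative", "nuclear_only", "cytoplasmic_only", "dual")),
    audit_no_cytoplasm = FALSE)
  s <- summarize_specimen(cls, "P9")
  expect_equal(s$n_cd4, 100L)
  expect_equal(s$pct_nfoxp3, 20)
  expect_equal(s$pct_cfoxp3, 10)
  expect_equal(s$pct_cd4foxp3, 30)
  expect_equal(s$n_dual, 0L)
  # class partition: counts over CD4+ classes sum to n_cd4
  tab <- table(cls$foxp3_class[cls$cd4_positive])
  expect_equal(sum(tab), s$n_cd4)
  # zero CD4+ cells -> NA percentages
  cls0 <- cls; cls0$cd4_positive <- FALSE
  s0 <- summarize_specimen(cls0, "P0")
  expect_equal(s0$n_cd4, 0L)
  expect_true(is.na(s0$pct_nfoxp3))
})

test_that("raising the multiplier k never increases positive counts", {
  gi <- generate_image(small_field_params(n_cells = 20L, seed = 41L))
  seg <- segment_field(gi$image)
  rec <- measure_cells(gi$image, seg)
  counts <- vapply(c(1.0, 1.7, 2.5, 4.0), function(k) {
    thr <- specimen_thresholds(rec, k)
    cls <- classify_cells(rec, thr$cd4, thr$foxp3_nuclear,
                          thr$foxp3_cytoplasmic)
    c(sum(cls$cd4_positive), sum(cls$foxp3_class != "negative"))
  }, numeric(2))
  expect_true(all(diff(counts[1, ]) <= 0))
  expect_true(all(diff(counts[2, ]) <= 0))
})

test_that("manual-vs-automatic validation reproduces known lines", {
  auto <- data.frame(neg = c(10, 20, 30, 40), pos = c(5, 9, 13, 17))
  fit <- validate_against_manual(auto, auto)
  expect_equal(fit$slope, rep(1, 3), tolerance = 1e-12)
  expect_equal(fit$r_squared, rep(1, 3), tolerance = 1e-12)
  # manual = 2 x auto, orientation auto ~ manual -> slope 0.5
  fit2 <- validate_against_manual(auto, auto * 2)
  expect_equal(fit2$slope, rep(0.5, 3), tolerance = 1e-12)
  # random counts match the normal-equations oracle
  set.seed(8)
  a <- data.frame(x = rpois(10, 30)); m <- data.frame(x = rpois(10, 30))
  got <- validate_against_manual(a, m)
  want <- oracle_ls(m$x, a$x)
  expect_equal(got$slope[1], want$slope, tolerance = 1e-10)
  expect_equal(got$r_squared[1], want$r_squared, tolerance = 1e-10)
  expect_error(validate_against_manual(a[1:2, , drop = FALSE],
                                       m[1:2, , drop = FALSE]), "3")
})
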
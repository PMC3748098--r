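#' Parameters for synthetic fluorescence-field simulation
#'
#' Describes one simulated microscopy field: elliptical DAPI-bright nuclei
#' with surrounding autofluorescent cell bodies on a dim background, a
#' configurable fraction of CD4+ cells, and configurable fractions of CD4+
#' cells whose FOXP3 signal is confined to the nucleus or to the cytoplasm
#' (compartment exclusivity is planted; `frac_dual` can plant dual-positive
#' cells to exercise the classifier's dual branch).
#'
#' Cells are placed on a jittered square grid so the minimum center
#' separation is guaranteed by construction; `min_separation` must exceed the
#' maximum nucleus diameter so that nuclei of distinct cells are disjoint and
#' every nucleus pixel is nearest its own center (overlapping cell bodies are
#' resolved to the nearest nucleus center).
#'
#' @param width,height field size in pixels.
#' @param n_cells number of cells to plant.
#' @param nucleus_diameter_range nucleus equivalent circular diameters
#'   (pixels), i.e. `2 * sqrt(area / pi)` — the same operational definition
#'   the segmentation size gate uses, so planted sizes map directly onto the
#'   20-50 px gate.  The ellipse's major axis is `d / sqrt(axis_ratio)`.
#' @param frac_cd4 fraction of cells that are CD4+.
#' @param frac_nfoxp3,frac_cfoxp3,frac_dual fractions of CD4+ cells with
#'   FOXP3 confined to the nucleus, confined to the cytoplasm, or present in
#'   both compartments; their sum must be <= 1.  Planted counts are the
#'   rounded fractions, not Bernoulli draws.
#' @param signal_levels named list of mean intensities: `dapi` (nucleus,
#'   blue), `cd4` (CD4+ cell body, green), `foxp3` (positive compartment,
#'   red), `autofluor` (CD4- cell body, green), `background` (all channels
#'   outside the relevant structures).
#' @param noise_sigma sd of additive Gaussian noise (intensity units); the
#'   result is clipped to [0, 1].
#' @param min_separation minimum distance between nucleus centers (pixels).
#' @param cell_margin_range the cell ellipse's semi-axes exceed the nucleus's
#'   by a margin sampled uniformly in this range (pixels).
#' @param axis_ratio_range nucleus minor/major axis ratio sampled uniformly
#'   in this range.
#' @param seed integer seed; identical seeds give bit-identical fields.
#' @return object of class `image_sim_params`.
#' @export
image_sim_params <- function(width = 512L, height = 512L, n_cells = 45L,
                             nucleus_diameter_range = c(20, 50),
                             frac_cd4 = 0.2, frac_nfoxp3 = 0.25,
                             frac_cfoxp3 = 0.10, frac_dual = 0,
                             signal_levels = list(dapi = 0.8, cd4 = 0.5,
                                                  foxp3 = 0.55,
                                                  autofluor = 0.15,
                                                  background = 0.05),
                             noise_sigma = 0.02, min_separation = 62,
                             cell_margin_range = c(5, 15),
                             axis_ratio_range = c(0.7, 1.0), seed = NULL) {
  stopifnot(width >= 8, height >= 8, n_cells >= 0,
            length(nucleus_diameter_range) == 2L,
            nucleus_diameter_range[1] > 0,
            nucleus_diameter_range[1] <= nucleus_diameter_range[2],
            noise_sigma >= 0, min_separation > 0,
            cell_margin_range[1] > 0,
            cell_margin_range[1] <= cell_margin_range[2],
            axis_ratio_range[1] > 0, axis_ratio_range[2] <= 1,
            axis_ratio_range[1] <= axis_ratio_range[2])
  for (f in c(frac_cd4, frac_nfoxp3, frac_cfoxp3, frac_dual))
    if (f < 0 || f > 1) stop("all fractions must lie in [0, 1]")
  if (frac_nfoxp3 + frac_cfoxp3 + frac_dual > 1)
    stop("frac_nfoxp3 + frac_cfoxp3 + frac_dual must be <= 1")
  need <- c("dapi", "cd4", "foxp3", "autofluor", "background")
  if (!all(need %in% names(signal_levels)))
    stop("signal_levels needs: ", paste(need, collapse = ", "))
  max_major <- nucleus_diameter_range[2] / sqrt(axis_ratio_range[1])
  if (min_separation <= max_major)
    stop(sprintf(paste0(
      "min_separation must exceed the maximum nucleus major axis (%.1f px) ",
      "to guarantee disjoint nuclei and nucleus-in-own-cell topology"),
      max_major))
  structure(list(width = as.integer(width), height = as.integer(height),
                 n_cells = as.integer(n_cells),
                 nucleus_diameter_range = nucleus_diameter_range,
                 frac_cd4 = frac_cd4, frac_nfoxp3 = frac_nfoxp3,
                 frac_cfoxp3 = frac_cfoxp3, frac_dual = frac_dual,
                 signal_levels = signal_levels, noise_sigma = noise_sigma,
                 min_separation = min_separation,
                 cell_margin_range = cell_margin_range,
                 axis_ratio_range = axis_ratio_range, seed = seed),
            class = "image_sim_params")
}

# jittered-grid centers guaranteeing min separation; error when infeasible
.place_centers <- function(p) {
  n <- p$n_cells
  if (n == 0L)
    return(matrix(numeric(0), 0L, 2L, dimnames = list(NULL, c("x", "y"))))
  margin <- p$nucleus_diameter_range[2] / sqrt(p$axis_ratio_range[1]) / 2 + 2
  uw <- p$width - 2 * margin
  uh <- p$height - 2 * margin
  nx <- ceiling(sqrt(n * uw / uh))
  ny <- ceiling(n / nx)
  px <- uw / nx
  py <- uh / ny
  if (min(px, py) < p$min_separation || uw <= 0 || uh <= 0)
    stop(sprintf(
      "cannot place %d cells at min_separation %.1f in a %dx%d field",
      n, p$min_separation, p$width, p$height))
  j <- (min(px, py) - p$min_separation) / 2
  grid <- expand.grid(ix = seq_len(nx), iy = seq_len(ny))
  grid <- grid[sample.int(nrow(grid), n), , drop = FALSE]
  cx <- margin + (grid$ix - 0.5) * px + runif(n, -j, j)
  cy <- margin + (grid$iy - 0.5) * py + runif(n, -j, j)
  cbind(x = cx, y = cy)
}

#' Generate one synthetic fluorescence field with ground truth
#'
#' Draws every planted cell as a filled nucleus ellipse (axis ratio sampled
#' in `axis_ratio_range`, random orientation) inside a concentric cell
#' ellipse whose semi-axes exceed the nucleus's by a sampled margin.  The
#' blue plane carries DAPI in nuclei; the green plane carries the
#' autofluorescent cell body (brighter if CD4+); the red plane carries FOXP3
#' confined to the nucleus, the cytoplasm, or both, per the cell's planted
#' class.  Additive Gaussian noise is applied and the result clipped to
#' [0, 1].  Class counts equal the rounded planted fractions exactly.
#'
#' @param params an [image_sim_params()] object.
#' @return list with `image` (a `multichannel_image`) and `truth`: a list of
#'   `cells` (data frame: cell_id, x, y, nucleus_diameter, cd4_status,
#'   foxp3_class), `nuclei` and `cell_bodies` (ground-truth label matrices;
#'   nuclei of distinct cells are disjoint, each nucleus is contained in its
#'   cell, overlapping bodies resolved to the nearest center).
#' @export
generate_image <- function(params = image_sim_params()) {
  stopifnot(inherits(params, "image_sim_params"))
  with_seed(params$seed, .generate_image_impl(params))
}

.generate_image_impl <- function(p) {
  h <- p$height; w <- p$width
  lv <- p$signal_levels
  red <- matrix(lv$background, h, w)
  green <- matrix(lv$background, h, w)
  blue <- matrix(lv$background, h, w)

  centers <- .place_centers(p)
  n <- nrow(centers)

  # planted classes: exact rounded counts
  n_cd4 <- round(p$frac_cd4 * n)
  cd4_ids <- if (n_cd4 > 0) sort(sample.int(n, n_cd4)) else integer(0)
  n_nf <- round(p$frac_nfoxp3 * n_cd4)
  n_cf <- round(p$frac_cfoxp3 * n_cd4)
  n_du <- round(p$frac_dual * n_cd4)
  cls <- rep("negative", n)
  if (n_cd4 > 0) {
    pool <- sample(cd4_ids)
    stopifnot(n_nf + n_cf + n_du <= n_cd4)
    cls[head(pool, n_nf)] <- "nuclear"
    if (n_cf > 0) cls[pool[(n_nf + 1):(n_nf + n_cf)]] <- "cytoplasmic"
    if (n_du > 0) cls[pool[(n_nf + n_cf + 1):(n_nf + n_cf + n_du)]] <- "dual"
  }
  cd4 <- seq_len(n) %in% cd4_ids

  diam <- if (n > 0) runif(n, p$nucleus_diameter_range[1],
                           p$nucleus_diameter_range[2]) else numeric(0)
  ratio <- if (n > 0) runif(n, p$axis_ratio_range[1],
                            p$axis_ratio_range[2]) else numeric(0)
  theta <- if (n > 0) runif(n, 0, pi) else numeric(0)
  margin <- if (n > 0) runif(n, p$cell_margin_range[1],
                             p$cell_margin_range[2]) else numeric(0)

  nuc_lab <- matrix(0L, h, w)
  cell_lab <- matrix(0L, h, w)
  cell_d2 <- matrix(Inf, h, w)  # squared distance to owning center

  ellipse_pixels <- function(cx, cy, a, b, th) {
    x0 <- max(1L, floor(cx - a)); x1 <- min(w, ceiling(cx + a))
    y0 <- max(1L, floor(cy - a)); y1 <- min(h, ceiling(cy + a))
    xs <- x0:x1; ys <- y0:y1
    dx <- outer(ys * 0, xs - cx, function(u, v) v) # len(ys) x len(xs)
    dy <- outer(ys - cy, xs * 0, function(u, v) u)
    u <- dx * cos(th) + dy * sin(th)
    v <- -dx * sin(th) + dy * cos(th)
    inside <- (u / a)^2 + (v / b)^2 <= 1
    idx <- which(inside)
    ri <- ys[(idx - 1L) %% length(ys) + 1L]
    ci <- xs[(idx - 1L) %/% length(ys) + 1L]
    cbind(row = ri, col = ci)
  }

  for (k in seq_len(n)) {
    # semi-axes from equivalent circular diameter: a*b = (d/2)^2, b/a = ratio
    a_n <- diam[k] / 2 / sqrt(ratio[k])
    b_n <- diam[k] / 2 * sqrt(ratio[k])
    a_c <- a_n + margin[k]
    b_c <- b_n + margin[k]
    cx <- centers[k, "x"]; cy <- centers[k, "y"]
    cpix <- ellipse_pixels(cx, cy, a_c, b_c, theta[k])
    d2 <- (cpix[, "row"] - cy)^2 + (cpix[, "col"] - cx)^2
    lin <- cpix[, "row"] + (cpix[, "col"] - 1L) * h
    take <- d2 < cell_d2[lin]        # nearest-center overlap resolution
    cell_lab[lin[take]] <- k
    cell_d2[lin[take]] <- d2[take]
    npix <- ellipse_pixels(cx, cy, a_n, b_n, theta[k])
    nlin <- npix[, "row"] + (npix[, "col"] - 1L) * h
    nuc_lab[nlin] <- k
    cell_lab[nlin] <- k              # nucleus always owned by its own cell
    cell_d2[nlin] <- 0
  }

  # paint channels from the resolved masks
  for (k in seq_len(n)) {
    cmask <- which(cell_lab == k)
    nmask <- which(nuc_lab == k)
    cyto <- setdiff(cmask, nmask)
    blue[nmask] <- lv$dapi
    green[cmask] <- if (cd4[k]) lv$cd4 else lv$autofluor
    if (cls[k] %in% c("nuclear", "dual")) red[nmask] <- lv$foxp3
    if (cls[k] %in% c("cytoplasmic", "dual")) red[cyto] <- lv$foxp3
  }

  if (p$noise_sigma > 0) {
    red <- red + rnorm(h * w, 0, p$noise_sigma)
    green <- green + rnorm(h * w, 0, p$noise_sigma)
    blue <- blue + rnorm(h * w, 0, p$noise_sigma)
  }
  clip <- function(x) matrix(pmin(pmax(x, 0), 1), h, w)

  truth_cells <- data.frame(
    cell_id = seq_len(n), x = centers[, "x"], y = centers[, "y"],
    nucleus_diameter = diam, cd4_status = cd4, foxp3_class = cls,
    stringsAsFactors = FALSE)

  list(image = multichannel_image(clip(red), clip(green), clip(blue)),
       truth = list(cells = truth_cells, nuclei = nuc_lab,
                    cell_bodies = cell_lab))
}

#' Parameters for synthetic case-control cohort simulation
#'
#' Marker percentages are drawn from Beta distributions scaled to [0, 100]
#' with a Gaussian copula supplying the within-arm correlation between
#' %nFOXP3+/CD4+ and %cFOXP3+/CD4+.  Defaults plant the reported
#' study structure: 19 cases / 30 controls; cases have higher nuclear and
#' lower cytoplasmic FOXP3 percentages with a strong positive
#' nuclear-cytoplasmic correlation, controls the reverse separation with no
#' correlation.  Covariate prevalences default to the study cohort's observed
#' marginals and are sampled independently of arm.
#'
#' @param n_cases,n_controls arm sizes (defaults 19 and 30).
#' @param case_nfoxp3,case_cfoxp3,control_nfoxp3,control_cfoxp3 length-2
#'   vectors of Beta shape parameters (shape1, shape2) for the scaled marker
#'   distributions in each arm.
#' @param case_correlation,control_correlation Gaussian-copula correlation
#'   between the two markers within each arm, in [-1, 1].
#' @param covariate_prevalence named list of category probability vectors for
#'   `age_group`, `gender`, `race`, `tobacco_alcohol`, `t_stage`, `grade`.
#' @param seed integer seed.
#' @return object of class `cohort_sim_params`.
#' @export
cohort_sim_params <- function(n_cases = 19L, n_controls = 30L,
                              case_nfoxp3 = c(3, 12),
                              case_cfoxp3 = c(1.56, 17.9),
                              control_nfoxp3 = c(1.56, 17.9),
                              control_cfoxp3 = c(2.84, 16.1),
                              case_correlation = 0.85,
                              control_correlation = 0,
                              covariate_prevalence = NULL, seed = NULL) {
  stopifnot(n_cases >= 1, n_controls >= 1)
  for (sh in list(case_nfoxp3, case_cfoxp3, control_nfoxp3, control_cfoxp3))
    if (length(sh) != 2L || any(sh <= 0))
      stop("Beta shape parameters must be two positive numbers")
  for (r in c(case_correlation, control_correlation))
    if (!is.finite(r) || r < -1 || r > 1)
      stop("correlations must lie in [-1, 1]")
  if (is.null(covariate_prevalence)) {
    covariate_prevalence <- list(
      age_group = c("<=63" = 26, ">=64" = 23) / 49,
      gender = c(male = 28, female = 21) / 49,
      race = c(white_non_hispanic = 32, hispanic = 16) / 48,
      tobacco_alcohol = c(neither = 14, alcohol = 4, tobacco = 11,
                          both = 18) / 47,
      t_stage = c(T1 = 34, T2 = 15) / 49,
      grade = c(well = 23, mod_poor = 24) / 47)
  }
  need <- c("age_group", "gender", "race", "tobacco_alcohol", "t_stage",
            "grade")
  if (!all(need %in% names(covariate_prevalence)))
    stop("covariate_prevalence needs: ", paste(need, collapse = ", "))
  structure(list(n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 case_nfoxp3 = case_nfoxp3, case_cfoxp3 = case_cfoxp3,
                 control_nfoxp3 = control_nfoxp3,
                 control_cfoxp3 = control_cfoxp3,
                 case_correlation = case_correlation,
                 control_correlation = control_correlation,
                 covariate_prevalence = covariate_prevalence, seed = seed),
            class = "cohort_sim_params")
}

# correlated (nfoxp3, cfoxp3) pair via Gaussian copula + scaled Beta margins
.draw_markers <- function(n, sh_n, sh_c, rho) {
  z1 <- rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
  data.frame(pct_nfoxp3 = 100 * qbeta(pnorm(z1), sh_n[1], sh_n[2]),
             pct_cfoxp3 = 100 * qbeta(pnorm(z2), sh_c[1], sh_c[2]))
}

#' Generate a synthetic case-control cohort table
#'
#' One row per patient: arm label, covariates, and marker percentages; the
#' derived offset ratio columns are appended by [ratio_transform_cohort()].
#'
#' @param params a [cohort_sim_params()] object.
#' @return data frame with columns `patient_id`, `arm` (factor
#'   control/case), the six covariate factors, `pct_nfoxp3`, `pct_cfoxp3`.
#' @export
generate_cohort <- function(params = cohort_sim_params()) {
  stopifnot(inherits(params, "cohort_sim_params"))
  with_seed(params$seed, {
    p <- params
    cases <- .draw_markers(p$n_cases, p$case_nfoxp3, p$case_cfoxp3,
                           p$case_correlation)
    ctrls <- .draw_markers(p$n_controls, p$control_nfoxp3, p$control_cfoxp3,
                           p$control_correlation)
    n <- p$n_cases + p$n_controls
    cov <- lapply(p$covariate_prevalence, function(pr) {
      lev <- names(pr)
      factor(sample(lev, n, replace = TRUE, prob = pr), levels = lev)
    })
    out <- data.frame(
      patient_id = sprintf("P%03d", seq_len(n)),
      arm = factor(rep(c("case", "control"), c(p$n_cases, p$n_controls)),
                   levels = c("control", "case")),
      stringsAsFactors = FALSE)
    for (nm in names(cov)) out[[nm]] <- cov[[nm]]
    out$pct_nfoxp3 <- c(cases$pct_nfoxp3, ctrls$pct_nfoxp3)
    out$pct_cfoxp3 <- c(cases$pct_cfoxp3, ctrls$pct_cfoxp3)
    out
  })
}
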
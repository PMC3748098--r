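# Independent brute-force oracles used to verify the package's operations.
# These deliberately reimplement each computation in the most literal way
# possible and share no code with the package internals.

# --- histogram threshold oracles -------------------------------------------

oracle_bin_counts <- function(plane, n_bins) {
  v <- as.numeric(plane)
  idx <- pmin(floor(v * n_bins) + 1L, n_bins)
  tabulate(idx, nbins = n_bins)
}

# exhaustive scan of the Kapur entropy-sum objective over all splits
oracle_kapur <- function(plane, n_bins = 256L) {
  counts <- oracle_bin_counts(plane, n_bins)
  p <- counts / sum(counts)
  if (sum(p > 0) < 2L) return(mean(as.numeric(plane)))
  best <- -Inf
  best_t <- NA_integer_
  for (t in seq_len(n_bins - 1L)) {
    p0 <- p[1:t]
    p1 <- p[(t + 1L):n_bins]
    w0 <- sum(p0); w1 <- sum(p1)
    if (w0 <= 0 || w1 <= 0) next
    q0 <- p0[p0 > 0] / w0
    q1 <- p1[p1 > 0] / w1
    obj <- -sum(q0 * log(q0)) - sum(q1 * log(q1))
    if (obj > best) {  # strict improvement => smallest tie kept
      best <- obj
      best_t <- t
    }
  }
  if (is.na(best_t)) return(mean(as.numeric(plane)))
  best_t / n_bins
}

# exhaustive scan of the Otsu between-class-variance objective
oracle_otsu <- function(plane, n_bins = 256L) {
  counts <- oracle_bin_counts(plane, n_bins)
  p <- counts / sum(counts)
  if (sum(p > 0) < 2L) return(mean(as.numeric(plane)))
  mids <- (seq_len(n_bins) - 0.5) / n_bins
  best <- -Inf
  best_t <- NA_integer_
  for (t in seq_len(n_bins - 1L)) {
    w0 <- sum(p[1:t]); w1 <- 1 - w0
    if (w0 <= 0 || w1 <= 0) next
    m0 <- sum(p[1:t] * mids[1:t]) / w0
    m1 <- sum(p[(t + 1L):n_bins] * mids[(t + 1L):n_bins]) / w1
    obj <- w0 * w1 * (m0 - m1)^2
    if (obj > best) {
      best <- obj
      best_t <- t
    }
  }
  if (is.na(best_t)) return(mean(as.numeric(plane)))
  best_t / n_bins
}

# --- propagation oracle -----------------------------------------------------

# value of m at (i - di, j - dj), padded with `fill`
.shift_mat <- function(m, di, dj, fill) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  si <- seq_len(nr) - di
  sj <- seq_len(nc) - dj
  ok_i <- si >= 1L & si <= nr
  ok_j <- sj >= 1L & sj <= nc
  out[ok_i, ok_j] <- m[si[ok_i], sj[ok_j]]
  out
}

# multi-source minimal-cost assignment by lexicographic (cost, distance)
# label-by-label relaxation to convergence; ties across seeds broken by
# (cost, distance, label)
oracle_propagate <- function(intensity, seeds, mask, lambda) {
  labs <- sort(unique(seeds[seeds > 0L]))
  domain <- mask | seeds > 0L
  dirs <- rbind(c(-1, 0, 1), c(1, 0, 1), c(0, -1, 1), c(0, 1, 1),
                c(-1, -1, sqrt(2)), c(-1, 1, sqrt(2)),
                c(1, -1, sqrt(2)), c(1, 1, sqrt(2)))
  res <- lapply(labs, function(lb) {
    cost <- matrix(Inf, nrow(seeds), ncol(seeds))
    dist <- matrix(Inf, nrow(seeds), ncol(seeds))
    cost[seeds == lb] <- 0
    dist[seeds == lb] <- 0
    repeat {
      changed <- FALSE
      for (d in seq_len(nrow(dirs))) {
        di <- dirs[d, 1]; dj <- dirs[d, 2]; len <- dirs[d, 3]
        sc <- .shift_mat(cost, di, dj, Inf)
        sdist <- .shift_mat(dist, di, dj, Inf)
        sI <- .shift_mat(intensity, di, dj, NA_real_)
        sdom <- .shift_mat(domain, di, dj, FALSE)
        ncost <- sc + abs(intensity - sI) + lambda * len
        ndist <- sdist + len
        upd <- domain & sdom & is.finite(ncost) &
          (ncost < cost | (ncost == cost & ndist < dist))
        upd[is.na(upd)] <- FALSE
        if (any(upd)) {
          cost[upd] <- ncost[upd]
          dist[upd] <- ndist[upd]
          changed <- TRUE
        }
      }
      if (!changed) break
    }
    list(cost = cost, dist = dist)
  })
  lab_out <- matrix(0L, nrow(seeds), ncol(seeds))
  gap <- matrix(Inf, nrow(seeds), ncol(seeds))  # margin to 2nd-best cost
  best_cost <- matrix(Inf, nrow(seeds), ncol(seeds))
  best_dist <- matrix(Inf, nrow(seeds), ncol(seeds))
  for (k in seq_along(labs)) {
    cost <- res[[k]]$cost
    dist <- res[[k]]$dist
    better <- cost < best_cost |
      (cost == best_cost & dist < best_dist)
    better[is.na(better)] <- FALSE
    gap <- pmin(gap, abs(cost - best_cost))
    best_cost[better] <- cost[better]
    best_dist[better] <- dist[better]
    lab_out[better] <- labs[k]
  }
  # near-tie band: pixels where two seeds' costs are within tolerance
  near_tie <- matrix(FALSE, nrow(seeds), ncol(seeds))
  if (length(labs) > 1L) {
    for (k in seq_along(labs)) {
      ck <- res[[k]]$cost
      other <- abs(ck - best_cost) < 1e-9 & lab_out != labs[k] &
        is.finite(ck)
      near_tie <- near_tie | other
    }
  }
  list(labels = lab_out, near_tie = near_tie)
}

# --- rank-sum enumeration oracle -------------------------------------------

# exact two-sided p by enumerating all C(n1+n2, n1) group assignments of the
# pooled (tie-free) values
oracle_wilcoxon_exact <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(length(pooled), n1)
  us <- apply(combs, 2, function(ix) sum(r[ix]) - n1 * (n1 + 1) / 2)
  p <- 2 * min(mean(us <= u_obs), mean(us >= u_obs))
  min(1, p)
}

# --- AUC / regression oracles ----------------------------------------------

# Mann-Whitney concordance over all case-control pairs
oracle_auc_pairwise <- function(marker, arm, positive = "case") {
  cases <- marker[arm == positive]
  controls <- marker[arm != positive]
  grid <- expand.grid(a = cases, b = controls)
  mean((grid$a > grid$b) + 0.5 * (grid$a == grid$b))
}

# least squares by the normal equations
oracle_ls <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  fitted <- X %*% beta
  ss_res <- sum((y - fitted)^2)
  ss_tot <- sum((y - mean(y))^2)
  list(intercept = beta[1], slope = beta[2], r_squared = 1 - ss_res / ss_tot)
}
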
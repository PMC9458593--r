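# Shared fixtures and independent brute-force oracles.
# Section pairs are generated in code (no stored images); frequently used
# small pairs are cached per test run.

.fixture_cache <- new.env(parent = emptyenv())

small_pair <- function(seed = 11L, truth = 30, delta = 7.8, size = 256L,
                       mpp = 4, ...) {
  key <- paste(seed, truth, delta, size, mpp, sep = "_")
  if (is.null(.fixture_cache[[key]])) {
    cfg <- section_sim_config(width_px = size, height_px = size,
                              microns_per_pixel = mpp,
                              true_fraction_pct = truth,
                              frozen_delta_pct = delta, seed = seed, ...)
    .fixture_cache[[key]] <- simulate_section_pair(cfg)
  }
  .fixture_cache[[key]]
}

# hand-built section: constant-colour raster with a rectangular cortex
# polygon (and optional exclusions), for exact-count tests
rect_section <- function(h = 20L, w = 20L, rgb = c(230L, 205L, 110L),
                         cortex = c(0, 0, w, h), exclusions = list(),
                         mpp = 1, kind = "paraffin") {
  px <- array(rep(rgb, each = h * w), dim = c(h, w, 3L))
  rect_poly <- function(b, role) annotation_polygon(
    c(b[1], b[3], b[3], b[1]), c(b[2], b[2], b[4], b[4]), role = role)
  anns <- c(list(rect_poly(cortex, "cortex")),
            lapply(exclusions, function(e) rect_poly(e$bounds, e$role)))
  section_image(px, mpp, kind, anns, "fixture")
}

# ---- oracles -------------------------------------------------------------

# brute-force even-odd point-in-polygon test for one point
bf_point_in_polygon <- function(px, py, xs, ys) {
  n <- length(xs); inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    if ((ys[i] <= py && ys[j] > py) || (ys[j] <= py && ys[i] > py)) {
      xint <- xs[i] + (py - ys[i]) * (xs[j] - xs[i]) / (ys[j] - ys[i])
      if (px < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

# explicit-sum Bland-Altman moments and OLS slope test
bf_bland_altman <- function(f, p) {
  n <- length(f); d <- f - p; m <- (f + p) / 2
  mean_d <- sum(d) / n
  sd_d <- sqrt(sum((d - mean_d)^2) / (n - 1))
  mx <- sum(m) / n
  beta <- sum((m - mx) * (d - mean_d)) / sum((m - mx)^2)
  a <- mean_d - beta * mx
  resid <- d - a - beta * m
  se <- sqrt(sum(resid^2) / (n - 2) / sum((m - mx)^2))
  tval <- beta / se
  list(mean_diff = mean_d, sd_diff = sd_d,
       loa = c(mean_d - 1.96 * sd_d, mean_d + 1.96 * sd_d),
       beta = beta, p = 2 * stats::pt(-abs(tval), n - 2))
}

# confusion-matrix evaluation of the quadratic-weighted kappa
bf_weighted_kappa <- function(a, b, levels) {
  K <- length(levels); n <- length(a)
  O <- matrix(0, K, K); E <- matrix(0, K, K); W <- matrix(0, K, K)
  for (i in seq_len(K)) for (j in seq_len(K)) {
    O[i, j] <- sum(a == levels[i] & b == levels[j]) / n
    W[i, j] <- ((i - j) / (K - 1))^2
  }
  pa <- rowSums(O); pb <- colSums(O)
  for (i in seq_len(K)) for (j in seq_len(K)) E[i, j] <- pa[i] * pb[j]
  1 - sum(W * O) / sum(W * E)
}

# exact Mann-Whitney two-sided p by exhaustive enumeration of group labels
bf_mann_whitney_exact <- function(x1, x2) {
  pooled <- c(x1, x2); n1 <- length(x1)
  u_stat <- function(g1) {
    r <- rank(pooled)
    sum(r[g1]) - n1 * (n1 + 1) / 2
  }
  u_obs <- u_stat(seq_len(n1))
  combos <- utils::combn(length(pooled), n1)
  u_all <- apply(combos, 2L, function(idx) {
    r <- rank(pooled); sum(r[idx]) - n1 * (n1 + 1) / 2
  })
  min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
}

# VIF via an explicit normal-equations solve for R^2
bf_vif <- function(X) {
  X <- as.matrix(X)
  vapply(seq_len(ncol(X)), function(j) {
    y <- X[, j]; Z <- cbind(1, X[, -j, drop = FALSE])
    beta <- solve(t(Z) %*% Z, t(Z) %*% y)
    r2 <- 1 - sum((y - Z %*% beta)^2) / sum((y - mean(y))^2)
    1 / (1 - r2)
  }, numeric(1L))
}

# logistic ML by direct numerical maximisation (independent of glm/IRLS)
bf_logistic <- function(y, X) {
  X1 <- cbind(1, as.matrix(X))
  nll <- function(b) {
    eta <- drop(X1 %*% b)
    sum(log1p(exp(eta))) - sum(y * eta)
  }
  grad <- function(b) {
    eta <- drop(X1 %*% b)
    drop(t(X1) %*% (stats::plogis(eta) - y))
  }
  b <- stats::optim(rep(0, ncol(X1)), nll, grad, method = "BFGS",
                    control = list(maxit = 1000, reltol = 1e-14))$par
  # polish to machine precision with explicit Newton steps
  for (it in 1:8) {
    p <- stats::plogis(drop(X1 %*% b))
    H <- t(X1) %*% (X1 * (p * (1 - p)))
    step <- solve(H, drop(t(X1) %*% (y - p)))
    b <- b + step
    if (max(abs(step)) < 1e-12) break
  }
  unname(b)
}
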
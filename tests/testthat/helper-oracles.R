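# Independent oracles used across the suite. These deliberately re-derive the
# operations from their definitions (loops, dense decompositions, direct
# formulas) so they share no code path with the package internals.

# brute-force histogram-equalization oracle: direct CDF mapping per pixel
oracle_equalize <- function(px) {
  px <- round(px)
  n <- length(px)
  cdf <- sapply(0:255, function(v) sum(px <= v))
  cdf_min <- min(cdf[cdf > 0])
  if (cdf_min == n) return(px)
  out <- px
  for (i in seq_along(px)) {
    out[i] <- round(255 * (cdf[px[i] + 1] - cdf_min) / (n - cdf_min))
  }
  out
}

# brute-force bilinear resize with half-pixel-centered sampling (pixel loops)
oracle_resize <- function(px, side) {
  h <- nrow(px); w <- ncol(px)
  out <- matrix(0, side, side)
  for (i in seq_len(side)) {
    for (j in seq_len(side)) {
      sy <- min(max((i - 0.5) * h / side + 0.5, 1), h)
      sx <- min(max((j - 0.5) * w / side + 0.5, 1), w)
      y0 <- min(floor(sy), h - 1); x0 <- min(floor(sx), w - 1)
      if (h == 1) y0 <- 1
      if (w == 1) x0 <- 1
      fy <- sy - y0; fx <- sx - x0
      y1 <- min(y0 + 1, h); x1 <- min(x0 + 1, w)
      out[i, j] <- (1 - fy) * (1 - fx) * px[y0, x0] + (1 - fy) * fx * px[y0, x1] +
        fy * (1 - fx) * px[y1, x0] + fy * fx * px[y1, x1]
    }
  }
  out
}

# bilinear rotation of an image about its center (source sampling; outside -> 0)
oracle_rotate <- function(img, theta) {
  s <- nrow(img); cc <- (s + 1) / 2
  out <- matrix(0, s, s)
  for (i in seq_len(s)) {
    for (j in seq_len(s)) {
      y <- i - cc; x <- j - cc
      xs <- x * cos(theta) + y * sin(theta)
      ys <- -x * sin(theta) + y * cos(theta)
      si <- ys + cc; sj <- xs + cc
      i0 <- floor(si); j0 <- floor(sj)
      if (i0 >= 1 && j0 >= 1 && i0 < s && j0 < s) {
        fy <- si - i0; fx <- sj - j0
        out[i, j] <- (1 - fy) * (1 - fx) * img[i0, j0] + (1 - fy) * fx * img[i0, j0 + 1] +
          fy * (1 - fx) * img[i0 + 1, j0] + fy * fx * img[i0 + 1, j0 + 1]
      }
    }
  }
  out
}

# unit-variance Laplace sample
rlaplace_unit <- function(n) {
  stats::rexp(n) * sample(c(-1, 1), n, replace = TRUE) / sqrt(2)
}

# small toy feature set with a planted discriminative structure
make_toy_features <- function(n_cand, n_per_class, seed, signal = 2) {
  set.seed(seed)
  y <- rep(c("mass", "non-mass"), each = n_per_class)
  FF <- matrix(rnorm(n_cand * 2 * n_per_class), n_cand)
  shift <- runif(n_cand, -signal, signal)
  FF[, y == "mass"] <- FF[, y == "mass"] + shift
  list(features = FF, labels = y)
}

# deterministic 2-class features with exactly isotropic within-class scatter
make_isotropic_classes <- function(mu1, mu2, a = 1) {
  p <- length(mu1)
  pts <- function(mu) {
    X <- matrix(mu, p, 2 * p)
    for (d in seq_len(p)) {
      X[d, 2 * d - 1] <- X[d, 2 * d - 1] + a
      X[d, 2 * d] <- X[d, 2 * d] - a
    }
    X
  }
  list(features = cbind(pts(mu1), pts(mu2)),
       labels = rep(c("mass", "non-mass"), each = 2 * p))
}

# exhaustive per-step oracle: at each growth step, brute-force every remaining
# candidate through the exported lda_fit / lda_predict route and take the
# argmax (lowest index on ties)
oracle_greedy <- function(FF, labels, n_select) {
  sel <- integer(0); scores <- numeric(0)
  remaining <- seq_len(nrow(FF))
  for (step in seq_len(n_select)) {
    accs <- vapply(remaining, function(j) {
      m <- lda_fit(FF[c(sel, j), , drop = FALSE], labels)
      mean(lda_predict(m, FF[c(sel, j), , drop = FALSE]) == labels)
    }, numeric(1))
    pick <- remaining[which.max(accs)]
    sel <- c(sel, pick)
    scores <- c(scores, max(accs))
    remaining <- remaining[remaining != pick]
  }
  list(selected_indices = sel, step_scores = scores)
}
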
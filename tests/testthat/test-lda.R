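test_that("isotropic classes with an axis-aligned mean shift force beta", {
  toy <- make_isotropic_classes(mu1 = c(1, 0), mu2 = c(0, 0))
  m <- lda_fit(toy$features, toy$labels)
  expect_equal(abs(m$beta), c(1, 0), tolerance = 1e-10)
  expect_equal(m$positive_class, "mass")
  # scatter matrices are symmetric PSD
  for (S in list(m$between_scatter, m$within_scatter)) {
    expect_equal(S, t(S), tolerance = 1e-10)
    expect_true(all(eigen(S, symmetric = TRUE, only.values = TRUE)$values > -1e-10))
  }
  expect_equal(sum(m$beta^2), 1, tolerance = 1e-12)
})

test_that("beta matches the dense-eigen and closed-form Fisher oracles", {
  set.seed(40)
  X <- cbind(matrix(rnorm(3 * 30), 3) + c(1, 2, 0), matrix(rnorm(3 * 25), 3))
  y <- rep(c("mass", "non-mass"), c(30, 25))
  m <- lda_fit(X, y)
  # oracle 1: top eigenvector of explicitly inverted W^-1 B
  eo <- eigen(solve(m$within_scatter) %*% m$between_scatter)
  v <- Re(eo$vectors[, which.max(Re(eo$values))]); v <- v / sqrt(sum(v^2))
  expect_lt(min(sum((m$beta - v)^2), sum((m$beta + v)^2)), 1e-16)
  # oracle 2: two-class closed form, pooled-Sigma^-1 (mean1 - mean2)
  cf <- solve(m$within_scatter, m$class_means[, "mass"] - m$class_means[, "non-mass"])
  cf <- cf / sqrt(sum(cf^2))
  expect_lt(min(sum((m$beta - cf)^2), sum((m$beta + cf)^2)), 1e-16)
  # fisher_ratio(beta) equals the top eigenvalue of the dense solve
  expect_equal(fisher_ratio(m$beta, m), max(Re(eo$values)), tolerance = 1e-8)
})

test_that("prediction follows the midpoint rule with negative ties", {
  toy <- make_isotropic_classes(mu1 = c(2, 0, 0), mu2 = c(0, 0, 0))
  m <- lda_fit(toy$features, toy$labels)
  expect_equal(lda_predict(m, cbind(c(2, 0, 0))), "mass")
  expect_equal(lda_predict(m, cbind(c(0, 0, 0))), "non-mass")
  # exactly at the midpoint of projected means: negative class by convention
  mid <- (m$class_means[, "mass"] + m$class_means[, "non-mass"]) / 2
  expect_equal(lda_predict(m, cbind(mid)), "non-mass")
  expect_error(lda_predict(m, matrix(1, 5, 1)), "dimension")
})

test_that("accuracy approaches the analytic Bayes rate on 2 Gaussians", {
  # centroid distance 4 sigma: Bayes accuracy = Phi(2)
  set.seed(41)
  n <- 5000
  Xtr <- cbind(matrix(rnorm(2 * n), 2) + c(4, 0), matrix(rnorm(2 * n), 2))
  y <- rep(c("mass", "non-mass"), c(n, n))
  m <- lda_fit(Xtr, y)
  Xte <- cbind(matrix(rnorm(2 * n), 2) + c(4, 0), matrix(rnorm(2 * n), 2))
  acc <- mean(lda_predict(m, Xte) == y)
  expect_lt(abs(acc - pnorm(2)), 0.02)
})

test_that("fisher_ratio is maximized at beta and is scale-invariant", {
  set.seed(42)
  X <- cbind(matrix(rnorm(4 * 40), 4) + c(1, 0, 1, 0), matrix(rnorm(4 * 40), 4))
  y <- rep(c("mass", "non-mass"), each = 40)
  m <- lda_fit(X, y)
  r_beta <- fisher_ratio(m$beta, m)
  for (i in 1:100) {
    d <- rnorm(4); d <- d / sqrt(sum(d^2))
    expect_lte(fisher_ratio(d, m), r_beta + 1e-10)
  }
  d <- rnorm(4)
  expect_equal(fisher_ratio(2 * d, m), fisher_ratio(d, m), tolerance = 1e-12)
  expect_error(fisher_ratio(c(0, 0, 0, 0), m), "nonzero")
})

test_that("identical class means give zero ratio in every direction", {
  # two classes, same mean, different scatter axes
  X <- cbind(c(1, 0), c(-1, 0), c(2, 0), c(-2, 0),
             c(0, 1), c(0, -1), c(0, 2), c(0, -2))
  y <- rep(c("mass", "non-mass"), each = 4)
  m <- lda_fit(X, y)
  expect_equal(fisher_ratio(c(1, 1), m), 0)
  expect_equal(fisher_ratio(c(-2, 3), m), 0)
})

test_that("predictions are invariant under invertible affine feature maps", {
  set.seed(43)
  X <- cbind(matrix(rnorm(3 * 50), 3) + c(2, 1, 0), matrix(rnorm(3 * 50), 3))
  y <- rep(c("mass", "non-mass"), each = 50)
  Xnew <- cbind(matrix(rnorm(3 * 20), 3) + c(1, 0.5, 0), matrix(rnorm(3 * 20), 3))
  m <- lda_fit(X, y)
  base_pred <- lda_predict(m, Xnew)
  Q <- matrix(c(2, 0.5, 0, -1, 1, 0.3, 0.2, 0, 1.5), 3, 3)  # invertible
  b <- c(5, -3, 2)
  m2 <- lda_fit(Q %*% X + b, y)
  expect_identical(lda_predict(m2, Q %*% Xnew + b), base_pred)
})

test_that("singular within-scatter is ridge-regularized, not fatal", {
  # 3 features, one an exact copy: W_LDA singular
  set.seed(44)
  X2 <- cbind(matrix(rnorm(2 * 20), 2) + c(1.5, 0), matrix(rnorm(2 * 20), 2))
  X <- rbind(X2, X2[1, ])
  y <- rep(c("mass", "non-mass"), each = 20)
  m <- lda_fit(X, y)
  expect_gt(m$ridge, 0)
  expect_true(all(lda_predict(m, X) %in% c("mass", "non-mass")))
})

test_that("predictions agree with an established LDA implementation", {
  skip_if_not_installed("MASS")
  set.seed(45)
  X <- cbind(matrix(rnorm(4 * 60), 4) + c(1, -1, 0.5, 0), matrix(rnorm(4 * 60), 4))
  y <- rep(c("mass", "non-mass"), each = 60)       # balanced: equal priors
  m <- lda_fit(X, y)
  Xte <- cbind(matrix(rnorm(4 * 30), 4) + c(0.5, -0.5, 0.25, 0),
               matrix(rnorm(4 * 30), 4))
  ref <- MASS::lda(t(X), grouping = y)
  ref_pred <- as.character(predict(ref, t(Xte))$class)
  expect_gt(mean(lda_predict(m, Xte) == ref_pred), 0.97)
})

test_that("label validation", {
  expect_error(lda_fit(matrix(1:10, 2), rep("a", 5)), "exactly 2 classes")
  expect_error(lda_fit(matrix(1:12, 2), c("a", "a", "b", "b", "c", "c")),
               "exactly 2 classes")
  expect_error(lda_fit(matrix(rnorm(8), 2), c("a", "a", "a", "b")),
               "at least 2 samples")
})
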
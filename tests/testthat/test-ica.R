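test_that("whitening yields exactly unit covariance on retained directions", {
  set.seed(20)
  X <- matrix(rnorm(6 * 200), 6, 200) * (1:6)   # anisotropic
  w <- whiten(X)
  n <- ncol(X)
  C <- tcrossprod(w$z) / (n - 1)
  expect_equal(C, diag(w$model$retained_rank), tolerance = 1e-6)
  # whitening o dewhitening = identity on the retained subspace
  expect_equal(w$model$whitening %*% w$model$dewhitening,
               diag(w$model$retained_rank), tolerance = 1e-6)
})

test_that("whitening an already-white sample is near-orthogonal", {
  set.seed(21)
  w <- whiten(matrix(rnorm(5 * 20000), 5))
  K <- w$model$whitening
  expect_lt(max(abs(crossprod(K) - diag(5))), 0.1)
})

test_that("rank deficiency is detected and degenerate input rejected", {
  set.seed(22)
  A <- matrix(rnorm(10 * 2), 10, 2)
  S <- matrix(rnorm(2 * 500), 2, 500)
  w <- whiten(A %*% S)
  expect_equal(w$model$retained_rank, 2L)
  expect_error(whiten(matrix(0, 4, 10)), "zero variance")
  # max_rank cap
  w3 <- whiten(matrix(rnorm(8 * 300), 8), max_rank = 3)
  expect_equal(w3$model$retained_rank, 3L)
})

test_that("negentropy approximation separates Gaussian from Laplacian", {
  set.seed(23)
  g <- rnorm(1e5)
  expect_lte(negentropy_approx(g), 1e-3)

  l <- rlaplace_unit(1e5)
  jl <- negentropy_approx(l)
  # quadrature oracle: J = (E[G(L)] - E[G(nu)])^2 for exact unit-variance laplace
  G <- function(u) abs(u) + log1p(exp(-2 * abs(u))) - log(2)
  e_lap <- integrate(function(x) G(x) * exp(-abs(x) * sqrt(2)) / sqrt(2),
                     -Inf, Inf)$value
  e_gau <- integrate(function(x) G(x) * dnorm(x), -Inf, Inf)$value
  j_expect <- (e_lap - e_gau)^2
  expect_gt(jl, negentropy_approx(g))
  expect_lt(abs(jl - j_expect), 0.5 * j_expect)

  # G is even: sign flip leaves the score unchanged
  expect_identical(negentropy_approx(-l), negentropy_approx(l))
  expect_error(negentropy_approx(rep(1, 10)), "zero-variance")
  expect_error(negentropy_approx(1), "at least 2")
})

test_that("FastICA recovers a known 2x2 Laplacian mixing", {
  set.seed(24)
  S <- rbind(rlaplace_unit(1e4), rlaplace_unit(1e4))
  A <- matrix(c(2, 1, 1, 1), 2, 2)
  w <- whiten(A %*% S)
  m <- fastica_fit(w, 2, seed = 5)
  expect_true(m$converged)
  W_total <- m$filters %*% w$model$whitening
  expect_lt(amari_index(W_total, A), 0.05)
})

test_that("estimated models satisfy the algebraic contracts", {
  set.seed(25)
  S <- rbind(rlaplace_unit(3000), rlaplace_unit(3000), rlaplace_unit(3000))
  X <- matrix(rnorm(9), 3, 3) %*% S
  w <- whiten(X)
  m <- fastica_fit(w, 3, seed = 2)
  # unit-norm rows in whitened coordinates
  expect_equal(sqrt(rowSums(m$filters^2)), rep(1, 3), tolerance = 1e-8)
  # filters . basis = identity on the retained subspace
  expect_equal((m$filters %*% w$model$whitening) %*% m$basis, diag(3),
               tolerance = 1e-6)
  # determinism under fixed seed
  m2 <- fastica_fit(w, 2, seed = 7)
  m3 <- fastica_fit(w, 2, seed = 7)
  expect_identical(m2$filters, m3$filters)
})

test_that("Gaussian data do not crash the fit and non-convergence is flagged", {
  set.seed(26)
  w <- whiten(matrix(rnorm(4 * 2000), 4))
  # independent directions are unidentifiable on Gaussians; the fit must
  # still return, and an unmet tolerance must be flagged, never fatal
  m <- fastica_fit(w, 4, max_iter = 5, tol = 1e-9, seed = 3)
  expect_s3_class(m, "ica_model")
  expect_false(m$converged)
  expect_equal(nrow(m$convergence_log), 5L)
  expect_equal(sqrt(rowSums(m$filters^2)), rep(1, 4), tolerance = 1e-8)
})

test_that("projection is linear and unmix-remix reconstructs whitened data", {
  d <- generate_dataset(c(mass = 20, `non-mass` = 20), synth_params(seed = 6))
  w <- whiten(d, max_rank = 10)
  m <- fastica_fit(w, 10, seed = 1, max_iter = 50)
  f <- ica_project(d, m)
  expect_equal(nrow(f$features), 10L)
  expect_identical(f$labels, d$labels)
  # full-rank round trip: W' (W z) = z
  expect_equal(crossprod(m$filters, f$features), w$z, tolerance = 1e-6)
  # linearity in centered data
  mu <- m$whiten$mean
  pr <- function(v) unname(ica_project(v + mu, m)$features)
  x1 <- d$data[, 1] - mu; x2 <- d$data[, 2] - mu
  expect_equal(pr(cbind(2 * x1 + 3 * x2)), 2 * pr(cbind(x1)) + 3 * pr(cbind(x2)),
               tolerance = 1e-8)
  expect_error(ica_project(d, m, selected = 11), "out-of-range")
})

test_that("amari index is zero for scaled permutations, positive otherwise", {
  P <- matrix(c(0, 2, -3, 0), 2, 2)           # scaled permutation
  expect_equal(amari_index(P, diag(2)), 0)
  set.seed(27)
  expect_gt(amari_index(matrix(rnorm(9), 3), diag(3)), 0.1)
})
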
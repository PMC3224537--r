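#' Whiten a dataset
#'
#' Centers the data and applies the eigenvalue-scaled principal-axis rotation
#' so the retained coordinates have exactly unit covariance — the
#' precondition under which FastICA's unit-norm constraint on each filter row
#' equals the unit-variance constraint on each projection. Directions whose
#' variance falls below `var_floor` times the largest eigenvalue are dropped;
#' `max_rank` optionally truncates further to the leading-variance subspace
#' (the usual dimension reduction before ICA when samples are scarce).
#'
#' @param data A [roi_dataset()] or matrix (samples in columns).
#' @param var_floor Relative eigenvalue threshold for rank truncation.
#' @param max_rank Optional cap on the retained dimension (`NULL` keeps every
#'   direction above the floor).
#' @return A list with `z` (whitened data, `retained_rank` x n) and `model`
#'   (class `whiten_model`: `mean`, `whitening`, `dewhitening`,
#'   `retained_rank`).
#' @export
whiten <- function(data, var_floor = 1e-8, max_rank = NULL) {
  X <- .as_data_matrix(data)
  n <- ncol(X)
  if (n < 2L) stop("whitening requires at least 2 samples", call. = FALSE)
  mu <- rowMeans(X)
  Xc <- X - mu
  sv <- svd(Xc)
  eig <- sv$d^2 / (n - 1)
  if (eig[1] <= 0) stop("data has zero variance (all-zero after centering)", call. = FALSE)
  keep <- eig > var_floor * eig[1] & eig > 1e-24 * eig[1]
  if (!is.null(max_rank)) keep <- keep & seq_along(eig) <= max_rank
  r <- sum(keep)
  U <- sv$u[, keep, drop = FALSE]
  d <- sqrt(eig[keep])
  K <- t(U) / d                 # r x p whitening
  Kinv <- U * rep(d, each = nrow(U))  # p x r dewhitening (pseudo-inverse of K)
  model <- structure(list(mean = mu, whitening = K, dewhitening = Kinv,
                          retained_rank = r, eigenvalues = eig[keep]),
                     class = "whiten_model")
  list(z = K %*% Xc, model = model)
}

# E[G(nu)] for a standard normal nu, per contrast function (computed once)
.gauss_expectation <- local({
  cache <- new.env(parent = emptyenv())
  function(contrast) {
    if (is.null(cache[[contrast]])) {
      G <- .contrast_fns(contrast)$G
      cache[[contrast]] <- stats::integrate(function(z) G(z) * stats::dnorm(z),
                                            -Inf, Inf)$value
    }
    cache[[contrast]]
  }
})

.contrast_fns <- function(contrast = c("logcosh", "exp")) {
  contrast <- match.arg(contrast)
  switch(contrast,
    logcosh = list(
      # stable log cosh: |u| + log1p(exp(-2|u|)) - log 2
      G = function(u) abs(u) + log1p(exp(-2 * abs(u))) - log(2),
      g = tanh,
      gprime = function(u) 1 - tanh(u)^2
    ),
    exp = list(
      G = function(u) -exp(-u^2 / 2),
      g = function(u) u * exp(-u^2 / 2),
      gprime = function(u) (1 - u^2) * exp(-u^2 / 2)
    )
  )
}

#' Approximate negentropy of a sample
#'
#' Negentropy measures the distance of a distribution from Gaussianity and is
#' what FastICA maximizes. It is approximated as
#' `J = (E[G(u)] - E[G(nu)])^2` with `u` the standardized sample, `nu`
#' standard normal, and `G` a non-quadratic contrast (default `log cosh`).
#' The Gaussian expectation is evaluated by quadrature.
#'
#' @param coeffs Numeric sample of projection coefficients (length >= 2).
#' @param contrast `"logcosh"` (default) or `"exp"`.
#' @return Non-negative scalar; 0 for an exactly Gaussian distribution.
#' @export
negentropy_approx <- function(coeffs, contrast = "logcosh") {
  if (length(coeffs) < 2L) stop("need at least 2 values", call. = FALSE)
  s <- stats::sd(coeffs)
  if (!is.finite(s) || s == 0) stop("zero-variance sample", call. = FALSE)
  u <- (coeffs - mean(coeffs)) / s
  fns <- .contrast_fns(contrast)
  (mean(fns$G(u)) - .gauss_expectation(contrast))^2
}

# symmetric decorrelation: W <- (W W^T)^{-1/2} W, via SVD
.sym_decorrelate <- function(W) {
  s <- svd(W)
  s$u %*% t(s$v)
}

#' Estimate independent components by fixed-point FastICA
#'
#' From-scratch FastICA with symmetric (parallel) orthogonalization: each
#' sweep updates every unit by the fixed-point rule
#' `w <- E[z g(w'z)] - E[g'(w'z)] w` and re-orthonormalizes the whole filter
#' matrix, so each unit vector `w_i` maximizes the non-Gaussianity
#' (approximate negentropy) of its projection. Convergence is declared when
#' `1 - |cos(angle)|` between successive rows falls below `tol` for every row.
#'
#' Non-convergence (e.g. on Gaussian data, where independent directions are
#' unidentifiable) does not raise an error: the returned model carries
#' `converged = FALSE` and the per-sweep log, and the caller decides.
#'
#' @param whitened Output of [whiten()] (or a bare whitened matrix, rows =
#'   retained dimensions, columns = samples).
#' @param n_components Number of units to estimate (<= retained rank).
#' @param contrast `"logcosh"` (default) or `"exp"`.
#' @param max_iter Maximum fixed-point sweeps.
#' @param tol Convergence tolerance on `1 - |cos(angle)|` per row.
#' @param seed RNG seed for the random orthonormal initialization.
#' @return An object of class `ica_model`: `filters` (unmixing matrix W in
#'   whitened coordinates, unit-norm rows), `basis` (mixing matrix A mapped
#'   back to the original pixel space when a whitening model is available),
#'   `whiten` (the [whiten()] model or `NULL`), `converged`, and
#'   `convergence_log` (tibble of per-sweep angle changes).
#' @export
fastica_fit <- function(whitened, n_components, contrast = "logcosh",
                        max_iter = 200L, tol = 1e-4, seed = 1L) {
  if (is.list(whitened) && !is.null(whitened$z)) {
    Z <- whitened$z; wm <- whitened$model
  } else {
    Z <- .as_feature_matrix(whitened); wm <- NULL
  }
  r <- nrow(Z); n <- ncol(Z)
  n_components <- as.integer(n_components)
  if (is.na(n_components) || n_components < 1L || n_components > r) {
    stop(sprintf("`n_components` must be in [1, %d] (retained rank)", r),
         call. = FALSE)
  }
  fns <- .contrast_fns(contrast)

  old_seed <- .save_rng()
  on.exit(.restore_rng(old_seed))
  set.seed(seed)
  W <- .sym_decorrelate(matrix(stats::rnorm(n_components * r), n_components, r))

  deltas <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    U <- W %*% Z
    gU <- fns$g(U)
    W1 <- tcrossprod(gU, Z) / n - rowMeans(fns$gprime(U)) * W
    W1 <- .sym_decorrelate(W1)
    delta <- max(1 - abs(rowSums(W1 * W)))
    deltas <- c(deltas, delta)
    W <- W1
    if (delta < tol) { converged <- TRUE; break }
  }

  basis <- if (!is.null(wm)) wm$dewhitening %*% t(W) else t(W)
  structure(list(filters = W, basis = basis, whiten = wm,
                 converged = converged, n_iter = length(deltas),
                 contrast = contrast, tol = tol, seed = as.integer(seed),
                 convergence_log = tibble::tibble(iter = seq_along(deltas),
                                                  delta = deltas)),
            class = "ica_model")
}

#' @export
print.ica_model <- function(x, ...) {
  cat(sprintf("<ica_model> %d components, contrast = %s, %s after %d sweeps\n",
              nrow(x$filters), x$contrast,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  invisible(x)
}

#' Project a dataset onto selected independent components
#'
#' Applies the selected unmixing filters (rows of W composed with the
#' whitening transform) to the centered samples, yielding the independent
#' coefficients `s` for those components. On the screen-film ROI benchmark
#' this package models, 41 selected components is the mass/non-mass default.
#'
#' @param data A [roi_dataset()] or matrix in the original pixel space.
#' @param model A fitted [fastica_fit()] model with a whitening model.
#' @param selected Integer indices of the components to use (1-based); rows of
#'   the output follow this order. Defaults to all components.
#' @return A [feature_matrix()] with `length(selected)` rows.
#' @export
ica_project <- function(data, model, selected = seq_len(nrow(model$filters))) {
  stopifnot(inherits(model, "ica_model"))
  if (is.null(model$whiten)) {
    stop("model was fitted on a bare matrix; projection needs the whitening model",
         call. = FALSE)
  }
  selected <- as.integer(selected)
  if (any(is.na(selected)) || any(selected < 1L) ||
      any(selected > nrow(model$filters))) {
    stop("`selected` contains out-of-range component indices", call. = FALSE)
  }
  X <- .as_data_matrix(data)
  Z <- model$whiten$whitening %*% (X - model$whiten$mean)
  feature_matrix(model$filters[selected, , drop = FALSE] %*% Z,
                 if (inherits(data, "roi_dataset")) data$labels else NULL)
}

#' Amari index between an estimated unmixing and a true mixing matrix
#'
#' Standard permutation-and-scale-invariant error of blind source separation:
#' 0 when `P = W A` is a scaled permutation, approaching 1 for unrelated
#' matrices.
#'
#' @param W Estimated unmixing matrix.
#' @param A True mixing matrix (same dimension).
#' @return Scalar in `[0, 1]`.
#' @export
amari_index <- function(W, A) {
  P <- abs(W %*% A)
  N <- nrow(P)
  rows <- sum(rowSums(P) / apply(P, 1, max) - 1)
  cols <- sum(colSums(P) / apply(P, 2, max) - 1)
  (rows + cols) / (2 * N * (N - 1))
}
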
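#' Fit a PCA eigenimage basis
#'
#' Subtracts the per-pixel mean, forms the sample covariance (with `1/(n-1)`
#' normalization) and eigendecomposes it; eigenpairs are returned sorted by
#' eigenvalue in descending order. The decomposition is computed through the
#' SVD of the centered data matrix, which is the covariance eigendecomposition
#' restricted to the directions of nonzero variance (at most `n - 1` of them
#' when samples are fewer than pixels). Each eigenvector's sign is fixed so
#' its largest-magnitude entry is positive.
#'
#' @param data A [roi_dataset()] or a numeric matrix with one sample per
#'   column.
#' @return An object of class `pca_basis` with `mean` (per-pixel average),
#'   `components` (orthonormal eigenvectors, one per column) and
#'   `eigenvalues` (variances, non-increasing).
#' @export
pca_fit <- function(data) {
  X <- .as_data_matrix(data)
  n <- ncol(X)
  if (n < 2L) stop("PCA requires at least 2 samples", call. = FALSE)
  mu <- rowMeans(X)
  Xc <- X - mu
  sv <- svd(Xc)
  eig <- sv$d^2 / (n - 1)
  eig[sv$d < max(sv$d[1], 1) * 1e-10] <- 0   # numerically null directions
  V <- sv$u
  # sign convention: largest-magnitude entry of each eigenvector positive
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  structure(list(mean = mu, components = V, eigenvalues = eig,
                 total_variance = sum(colSums(Xc^2)) / (n - 1)),
            class = "pca_basis")
}

#' @export
print.pca_basis <- function(x, ...) {
  cat(sprintf("<pca_basis> %d components in %d dims; top eigenvalues: %s\n",
              ncol(x$components), length(x$mean),
              paste(signif(utils::head(x$eigenvalues, 3), 4), collapse = ", ")))
  invisible(x)
}

#' Project a dataset onto the leading principal components
#'
#' Centers each sample by the *training* mean stored in the basis and projects
#' onto the first `k` eigenvectors (variance order). With `k = 39` this is the
#' component count at which the PCA pipeline peaks on the screen-film ROI
#' benchmark this package models.
#'
#' @param data A [roi_dataset()] or matrix (samples in columns).
#' @param basis A fitted [pca_fit()] basis of matching dimensionality.
#' @param k Number of leading components, `1 <= k <= ncol(basis$components)`.
#' @return A [feature_matrix()] with `k` rows, labels carried over when the
#'   input is a `roi_dataset`.
#' @export
pca_project <- function(data, basis, k = 39L) {
  stopifnot(inherits(basis, "pca_basis"))
  X <- .as_data_matrix(data)
  if (nrow(X) != length(basis$mean)) {
    stop("data dimensionality does not match the basis", call. = FALSE)
  }
  k <- as.integer(k)
  if (is.na(k) || k < 1L || k > ncol(basis$components)) {
    stop(sprintf("`k` must be in [1, %d]", ncol(basis$components)), call. = FALSE)
  }
  Y <- crossprod(basis$components[, seq_len(k), drop = FALSE], X - basis$mean)
  feature_matrix(Y, if (inherits(data, "roi_dataset")) data$labels else NULL)
}
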
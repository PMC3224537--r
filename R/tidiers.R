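#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy per-fold cross-validation results
#'
#' @param x A `cad_eval` object from [crossvalidate()].
#' @param ... Unused.
#' @return A tibble with one row per fold: confusion counts and metrics.
#' @export
tidy.cad_eval <- function(x, ...) x$per_fold

#' One-row summary of a cross-validation run
#'
#' @param x A `cad_eval` object from [crossvalidate()].
#' @param ... Unused.
#' @return A one-row tibble: method, components, folds, fold-mean metrics.
#' @export
glance.cad_eval <- function(x, ...) {
  tibble::tibble(method = x$config$method,
                 n_components = x$config$n_components,
                 k = x$config$k,
                 accuracy = x$mean_accuracy,
                 sensitivity = x$mean_sensitivity,
                 specificity = x$mean_specificity)
}

#' Tidy a PCA basis
#'
#' @param x A `pca_basis` from [pca_fit()].
#' @param ... Unused.
#' @return A tibble with `component`, `eigenvalue` and the cumulative
#'   variance proportion.
#' @export
tidy.pca_basis <- function(x, ...) {
  tibble::tibble(component = seq_along(x$eigenvalues),
                 eigenvalue = x$eigenvalues,
                 cum_variance_prop = cumsum(x$eigenvalues) / x$total_variance)
}

#' One-row summary of a FastICA fit
#'
#' @param x An `ica_model` from [fastica_fit()].
#' @param ... Unused.
#' @return A one-row tibble: component count, contrast, convergence status,
#'   sweeps used and final row-angle change.
#' @export
glance.ica_model <- function(x, ...) {
  tibble::tibble(n_components = nrow(x$filters),
                 contrast = x$contrast,
                 converged = x$converged,
                 n_iter = x$n_iter,
                 final_delta = utils::tail(x$convergence_log$delta, 1))
}

#' Tidy a fitted discriminant
#'
#' @param x An `lda_model` from [lda_fit()].
#' @param ... Unused.
#' @return A tibble with one row per feature dimension and its `beta` weight.
#' @export
tidy.lda_model <- function(x, ...) {
  tibble::tibble(term = sprintf("feature_%d", seq_along(x$beta)),
                 beta = x$beta)
}

#' One-row summary of a fitted discriminant
#'
#' @param x An `lda_model` from [lda_fit()].
#' @param ... Unused.
#' @return A one-row tibble: dimension, threshold, positive class, Fisher
#'   ratio attained by `beta`, ridge used (0 when none).
#' @export
glance.lda_model <- function(x, ...) {
  tibble::tibble(dim = length(x$beta),
                 threshold = x$threshold,
                 positive_class = x$positive_class,
                 fisher_ratio = fisher_ratio(x$beta, x),
                 ridge = x$ridge)
}

#' Plot metric curves of a component sweep
#'
#' Accuracy, sensitivity and specificity (fold means) against the number of
#' components, one line per metric.
#'
#' @param object A `cad_sweep` tibble from [component_sweep()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cad_sweep <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              cols = c("accuracy", "sensitivity", "specificity"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$n_components, y = .data$value,
                                     colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "number of components", y = "fold-mean metric",
                  title = sprintf("%s component sweep", object$method[1])) +
    ggplot2::theme_minimal()
}

#' Montage of basis functions or filters
#'
#' Reshapes the first `n` columns of a basis set back into square images and
#' draws them as a raster montage (the usual way eigenimage / ICA-filter /
#' Gabor families are displayed).
#'
#' @param object A [basis_set()] (or an object with `$vectors`), or a
#'   `pca_basis` / `ica_model` whose columns live on a square grid.
#' @param n Number of leading basis vectors to show (default up to 50).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.basis_set <- function(object, n = 50L, ...) {
  V <- object$vectors
  .basis_montage(V, n)
}

#' @rdname autoplot.basis_set
#' @export
autoplot.pca_basis <- function(object, n = 50L, ...) {
  .basis_montage(object$components, n)
}

#' @rdname autoplot.basis_set
#' @export
autoplot.ica_model <- function(object, n = 50L, ...) {
  .basis_montage(object$basis, n)
}

.basis_montage <- function(V, n) {
  n <- min(n, ncol(V))
  side <- as.integer(round(sqrt(nrow(V))))
  if (side^2 != nrow(V)) {
    stop("basis vectors do not live on a square grid", call. = FALSE)
  }
  df <- purrr::map(seq_len(n), function(j) {
    img <- matrix(V[, j], side, side, byrow = TRUE)
    tibble::tibble(basis = j,
                   row = rep(seq_len(side), each = side),
                   col = rep(seq_len(side), times = side),
                   value = as.vector(t(img)))
  }) |> dplyr::bind_rows()
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = -.data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~basis) +
    ggplot2::scale_fill_gradient(low = "black", high = "white", guide = "none") +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}
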
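#' Greedy pursuit-style basis selection
#'
#' Grows a subspace Psi one basis at a time: at each step, every remaining
#' candidate basis is tentatively appended, the training data are projected
#' onto `[Psi; A_k]`, a Fisher discriminant is fitted, and the candidate
#' giving the best training-set score is kept. This wrapper selection is what
#' orders ICA basis functions and Gabor filters by discriminative value
#' (PCA components are instead ordered by variance and never pass through
#' here). Ties are broken toward the lowest candidate index.
#'
#' @param candidates Either a [basis_set()] (then `data` must be supplied and
#'   candidate coefficients are computed as inner products), or a
#'   precomputed coefficient matrix with one row per candidate and one column
#'   per training sample.
#' @param labels Two-class labels, one per training sample (taken from a
#'   labeled input when omitted).
#' @param n_select Number of bases to select, `1 <= n_select <= #candidates`.
#' @param criterion Training metric to maximize; `"accuracy"` (the default
#'   and the faithful choice) or `"youden"` (sensitivity + specificity - 1,
#'   an optional internal criterion).
#' @param data Training [roi_dataset()] or matrix, required when `candidates`
#'   is a `basis_set`.
#' @param positive_class Positive label for the internal discriminants.
#' @return An object of class `selection_result`: `selected_indices` (ordered,
#'   1-based, unique), `step_scores` (training score after each growth step)
#'   and `criterion`.
#' @export
select_bases <- function(candidates, labels = NULL, n_select,
                         criterion = c("accuracy", "youden"),
                         data = NULL, positive_class = NULL) {
  criterion <- match.arg(criterion)
  if (inherits(candidates, "basis_set")) {
    if (is.null(data)) {
      stop("`data` is required when `candidates` is a basis_set", call. = FALSE)
    }
    FF <- crossprod(candidates$vectors, .as_data_matrix(data))
    if (is.null(labels) && inherits(data, "roi_dataset")) labels <- data$labels
  } else if (inherits(candidates, "feature_matrix")) {
    FF <- candidates$features
    if (is.null(labels)) labels <- candidates$labels
  } else {
    FF <- .as_feature_matrix(candidates)
  }
  if (is.null(labels)) stop("`labels` are required", call. = FALSE)
  labels <- as.character(labels)
  if (length(labels) != ncol(FF)) {
    stop("`labels` length must match the number of training samples", call. = FALSE)
  }
  classes <- sort(unique(labels))
  if (length(classes) != 2L) {
    stop("selection requires exactly 2 classes in `labels`", call. = FALSE)
  }
  n_cand <- nrow(FF)
  n_select <- as.integer(n_select)
  if (is.na(n_select) || n_select < 1L || n_select > n_cand) {
    stop(sprintf("`n_select` must be in [1, %d]", n_cand), call. = FALSE)
  }
  if (is.null(positive_class)) {
    positive_class <- if ("mass" %in% classes) "mass"
      else if ("malignant" %in% classes) "malignant"
      else classes[1]
  }
  y <- labels == positive_class

  score_fn <- if (criterion == "accuracy") {
    function(X) .lda_train_accuracy(X, y)
  } else {
    function(X) .lda_train_youden(X, y)
  }

  sel <- integer(0)
  scores <- numeric(0)
  remaining <- seq_len(n_cand)
  for (step in seq_len(n_select)) {
    best <- -Inf; best_j <- NA_integer_
    for (j in remaining) {           # ascending order + strict '>' = lowest-index ties
      sc <- score_fn(FF[c(sel, j), , drop = FALSE])
      if (sc > best) { best <- sc; best_j <- j }
    }
    sel <- c(sel, best_j)
    remaining <- remaining[remaining != best_j]
    scores <- c(scores, best)
  }
  structure(list(selected_indices = sel, step_scores = scores,
                 criterion = criterion),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %d bases by %s; first: %s; final score %.4f\n",
              length(x$selected_indices), x$criterion,
              paste(utils::head(x$selected_indices, 8), collapse = ", "),
              utils::tail(x$step_scores, 1)))
  invisible(x)
}

.lda_train_youden <- function(X, y) {
  p <- nrow(X)
  m1 <- rowMeans(X[, y, drop = FALSE])
  m0 <- rowMeans(X[, !y, drop = FALSE])
  X1 <- X[, y, drop = FALSE] - m1
  X0 <- X[, !y, drop = FALSE] - m0
  Wl <- tcrossprod(X1) + tcrossprod(X0)
  beta <- tryCatch(solve(Wl, m1 - m0),
                   error = function(e) {
                     solve(Wl + diag(1e-6 * (sum(diag(Wl)) / p + 1), p), m1 - m0)
                   })
  s <- drop(crossprod(beta, X))
  thr <- (sum(beta * m1) + sum(beta * m0)) / 2
  pred <- s > thr
  sens <- mean(pred[y]); spec <- mean(!pred[!y])
  sens + spec - 1
}
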
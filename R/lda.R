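#' Fit a Fisher linear discriminant
#'
#' Two-class Fisher LDA from the scatter-matrix formulation: the
#' between-group scatter `B = sum_i n_i (xbar_i - xbar)(xbar_i - xbar)'` and
#' the within-group scatter `W = sum_i n_i Sigma_i` (class covariances pooled
#' with `n_i` weights) are formed, and the discriminant direction `beta` is
#' the eigenvector of `W^-1 B` with the largest eigenvalue — the direction
#' maximizing the ratio of between- to within-group sum-of-squares. If `W` is
#' singular it is ridge-regularized by `lambda * tr(W)/p * I` with
#' `lambda = 1e-6`.
#'
#' `beta` is normalized to unit length and oriented so the positive class has
#' the larger projected mean; the decision threshold is the midpoint of the
#' projected class means (equal-prior Fisher rule).
#'
#' @param features A [feature_matrix()] or matrix (features x samples).
#' @param labels Class labels (exactly 2 classes, each with >= 2 samples);
#'   taken from `features` when it is a labeled `feature_matrix`.
#' @param positive_class Label treated as "positive" ("mass"-like). Defaults
#'   to `"mass"` or `"malignant"` when present, else the first sorted label.
#' @return An object of class `lda_model` with `beta`, `between_scatter`,
#'   `within_scatter`, `class_means`, `grand_mean`, `threshold`,
#'   `positive_class`, `negative_class`, `n_per_class`, `ridge`.
#' @export
lda_fit <- function(features, labels = NULL, positive_class = NULL) {
  X <- .as_feature_matrix(features)
  if (is.null(labels) && inherits(features, "feature_matrix")) {
    labels <- features$labels
  }
  if (is.null(labels)) stop("`labels` are required", call. = FALSE)
  labels <- as.character(labels)
  if (length(labels) != ncol(X)) {
    stop("`labels` length must match the number of samples", call. = FALSE)
  }
  classes <- sort(unique(labels))
  if (length(classes) != 2L) {
    stop(sprintf("LDA requires exactly 2 classes (got %d)", length(classes)),
         call. = FALSE)
  }
  n_i <- table(factor(labels, levels = classes))
  if (any(n_i < 2L)) stop("each class needs at least 2 samples", call. = FALSE)

  if (is.null(positive_class)) {
    positive_class <- if ("mass" %in% classes) "mass"
      else if ("malignant" %in% classes) "malignant"
      else classes[1]
  }
  if (!positive_class %in% classes) {
    stop(sprintf("positive_class '%s' not among the labels", positive_class),
         call. = FALSE)
  }
  negative_class <- setdiff(classes, positive_class)

  p <- nrow(X)
  gm <- rowMeans(X)
  M <- matrix(vapply(classes, function(cl) rowMeans(X[, labels == cl, drop = FALSE]),
                     numeric(p)),
              nrow = p, dimnames = list(NULL, classes))
  B <- matrix(0, p, p); Wl <- matrix(0, p, p)
  for (j in seq_along(classes)) {
    dm <- M[, j] - gm
    B <- B + as.numeric(n_i[j]) * tcrossprod(dm)
    Xi <- X[, labels == classes[j], drop = FALSE] - M[, j]
    Wl <- Wl + tcrossprod(Xi)   # = n_i * Sigma_i with Sigma_i = scatter / n_i
  }

  ridge <- 0
  ev_w <- eigen(Wl, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev_w) < 1e-10 * max(abs(ev_w), 1)) {
    ridge <- 1e-6 * sum(diag(Wl)) / p
    if (ridge <= 0) ridge <- 1e-6
    Wl_use <- Wl + diag(ridge, p)
    if (min(eigen(Wl_use, symmetric = TRUE, only.values = TRUE)$values) <= 0) {
      stop("within-group scatter is degenerate even after regularization",
           call. = FALSE)
    }
  } else {
    Wl_use <- Wl
  }

  ev <- eigen(solve(Wl_use) %*% B)
  beta <- Re(ev$vectors[, which.max(Re(ev$values))])
  beta <- beta / sqrt(sum(beta^2))
  mu_pos <- sum(beta * M[, positive_class])
  mu_neg <- sum(beta * M[, negative_class])
  if (mu_pos < mu_neg) {
    beta <- -beta
    mu_pos <- -mu_pos
    mu_neg <- -mu_neg
  }

  structure(list(beta = beta, between_scatter = B, within_scatter = Wl,
                 class_means = M, grand_mean = gm,
                 threshold = (mu_pos + mu_neg) / 2,
                 positive_class = positive_class,
                 negative_class = negative_class,
                 n_per_class = as.integer(n_i), ridge = ridge),
            class = "lda_model")
}

#' @export
print.lda_model <- function(x, ...) {
  cat(sprintf("<lda_model> %d-dim discriminant; positive = '%s', threshold = %.4g\n",
              length(x$beta), x$positive_class, x$threshold))
  invisible(x)
}

#' Classify samples with a fitted discriminant
#'
#' Assigns the positive class iff `beta' x > threshold`; a sample projecting
#' exactly onto the threshold is assigned to the negative (non-mass) class.
#'
#' @param model A fitted [lda_fit()] model.
#' @param features A [feature_matrix()] or matrix of matching dimension.
#' @return Character vector of predicted labels.
#' @export
lda_predict <- function(model, features) {
  stopifnot(inherits(model, "lda_model"))
  X <- .as_feature_matrix(features)
  if (nrow(X) != length(model$beta)) {
    stop("feature dimension does not match the model", call. = FALSE)
  }
  scores <- unname(drop(crossprod(model$beta, X)))
  ifelse(scores > model$threshold, model$positive_class, model$negative_class)
}

#' Fisher criterion of a direction
#'
#' The ratio `(d' B d) / (d' W d)` of between- to within-group sum-of-squares
#' along a direction `d`; scale-invariant in `d` and maximized by the fitted
#' `beta`.
#'
#' @param direction Nonzero numeric vector.
#' @param model A fitted [lda_fit()] model.
#' @return Scalar ratio.
#' @export
fisher_ratio <- function(direction, model) {
  stopifnot(inherits(model, "lda_model"))
  d <- as.numeric(direction)
  if (all(d == 0)) stop("`direction` must be nonzero", call. = FALSE)
  num <- drop(t(d) %*% model$between_scatter %*% d)
  den <- drop(t(d) %*% model$within_scatter %*% d)
  if (num == 0) return(0)
  num / den
}

# internal fast path used by the greedy selection loop: training accuracy of
# a two-class Fisher discriminant on a small feature matrix. y must be a
# logical vector (TRUE = positive class).
.lda_train_accuracy <- function(X, y) {
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
  mean(pred == y)
}
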
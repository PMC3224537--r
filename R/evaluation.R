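#' Confusion-matrix metrics
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)` and accuracy
#' `(TP+TN)/(TP+TN+FP+FN)`, with "positive" meaning the mass-like class. A
#' ratio with an empty denominator is reported as `NA` (absent), never as 0.
#'
#' @param counts A list, one-row data frame or named vector with `TP`, `TN`,
#'   `FP`, `FN`.
#' @return A one-row tibble with `accuracy`, `sensitivity`, `specificity`.
#' @export
compute_metrics <- function(counts) {
  cc <- as.list(counts)
  need <- c("TP", "TN", "FP", "FN")
  if (!all(need %in% names(cc))) {
    stop("`counts` must provide TP, TN, FP, FN", call. = FALSE)
  }
  v <- vapply(cc[need], as.numeric, numeric(1))
  if (any(v < 0) || any(v != round(v))) {
    stop("confusion counts must be non-negative integers", call. = FALSE)
  }
  v <- unname(v)   # TP, TN, FP, FN
  total <- sum(v)
  tibble::tibble(
    accuracy    = if (total > 0) (v[1] + v[2]) / total else NA_real_,
    sensitivity = if (v[1] + v[4] > 0) v[1] / (v[1] + v[4]) else NA_real_,
    specificity = if (v[2] + v[3] > 0) v[2] / (v[2] + v[3]) else NA_real_
  )
}

.confusion_counts <- function(truth, pred, positive) {
  tp <- sum(truth == positive & pred == positive)
  tn <- sum(truth != positive & pred != positive)
  fp <- sum(truth != positive & pred == positive)
  fn <- sum(truth == positive & pred != positive)
  list(TP = tp, TN = tn, FP = fp, FN = fn)
}

#' Stratified k-fold assignment
#'
#' Randomly (but reproducibly) assigns every sample to one of `k` folds so
#' that per-class counts differ by at most one across folds. With 3240 mass
#' and 1850 non-mass samples and `k = 10`, every fold holds exactly 324 mass
#' and 185 non-mass samples (509 test / 4581 train per round).
#'
#' @param labels Class labels, one per sample.
#' @param k Number of folds (every class must have at least `k` members).
#' @param seed RNG seed for the shuffle.
#' @return Integer vector of fold ids in `1..k`, one per sample.
#' @export
stratified_kfold <- function(labels, k = 10L, seed = 1L) {
  labels <- as.character(labels)
  k <- as.integer(k)
  stopifnot(k >= 2L)
  tab <- table(labels)
  if (any(tab < k)) {
    stop(sprintf("class '%s' has fewer than k = %d samples",
                 names(tab)[which.min(tab)], k), call. = FALSE)
  }
  old_seed <- .save_rng()
  on.exit(.restore_rng(old_seed))
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in names(tab)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Feature-extractor configurations
#'
#' Constructors for the three extraction routes a cross-validation run can
#' use. `extractor_pca()` orders components by variance; `extractor_ica()`
#' fits FastICA on the whitened training fold and greedily selects the most
#' discriminative components; `extractor_gabor()` projects onto a fixed
#' filter bank and greedily selects filters.
#'
#' @param n_candidates ICA: the training fold is whitened and reduced to this
#'   many leading-variance dimensions and a square FastICA rotation is
#'   estimated there; the greedy selection then picks from these components.
#'   `NULL` keeps the full whitened rank (a full-rank basis, appropriate when
#'   training samples comfortably outnumber pixels). The default pool of a
#'   few dozen suits studies of a few hundred samples: a wrapper selection
#'   that scans a candidate pool approaching `n_train / 10` starts to overfit
#'   the training criterion.
#' @param contrast,max_iter,tol,var_floor FastICA / whitening options, see
#'   [fastica_fit()] and [whiten()].
#' @param params Gabor: a [gabor_params()] bank specification.
#' @return An object of class `cad_extractor`.
#' @name extractors
NULL

#' @rdname extractors
#' @export
extractor_pca <- function() {
  structure(list(kind = "pca"), class = "cad_extractor")
}

#' @rdname extractors
#' @export
extractor_ica <- function(n_candidates = 24L, contrast = "logcosh",
                          max_iter = 200L, tol = 1e-4, var_floor = 1e-8) {
  structure(list(kind = "ica",
                 n_candidates = if (is.null(n_candidates)) NULL
                                else as.integer(n_candidates),
                 contrast = contrast, max_iter = as.integer(max_iter),
                 tol = tol, var_floor = var_floor),
            class = "cad_extractor")
}

#' @rdname extractors
#' @export
extractor_gabor <- function(params = gabor_params()) {
  structure(list(kind = "gabor", params = params, bank = gabor_bank(params)),
            class = "cad_extractor")
}

# fit the extractor on the training fold only and return the ordered
# candidate features for train and test (ordering = variance for PCA,
# greedy-selection order for ICA/Gabor, truncated at n_order).
.fold_features <- function(ex, X, labels, tr_idx, te_idx, n_order, seed,
                           positive_class) {
  Xtr <- X[, tr_idx, drop = FALSE]
  Xte <- X[, te_idx, drop = FALSE]
  ytr <- labels[tr_idx]
  if (ex$kind == "pca") {
    b <- pca_fit(Xtr)
    k <- min(n_order, ncol(b$components))
    list(train = pca_project(Xtr, b, k)$features,
         test  = pca_project(Xte, b, k)$features,
         order = seq_len(k))
  } else if (ex$kind == "ica") {
    wh <- whiten(Xtr, ex$var_floor, max_rank = ex$n_candidates)
    nc <- wh$model$retained_rank
    m <- fastica_fit(wh, nc, contrast = ex$contrast,
                     max_iter = ex$max_iter, tol = ex$tol, seed = seed)
    Ftr <- m$filters %*% wh$z
    k <- min(n_order, nc)
    sel <- select_bases(Ftr, ytr, k, positive_class = positive_class)
    list(train = Ftr[sel$selected_indices, , drop = FALSE],
         test  = ica_project(Xte, m, sel$selected_indices)$features,
         order = sel$selected_indices)
  } else if (ex$kind == "gabor") {
    mu <- rowMeans(Xtr)
    Ftr <- crossprod(ex$bank$vectors, Xtr - mu)
    k <- min(n_order, ncol(ex$bank$vectors))
    sel <- select_bases(Ftr, ytr, k, positive_class = positive_class)
    list(train = Ftr[sel$selected_indices, , drop = FALSE],
         test  = gabor_project(Xte, ex$bank, sel$selected_indices,
                               center = mu)$features,
         order = sel$selected_indices)
  } else {
    stop(sprintf("unknown extractor kind '%s'", ex$kind), call. = FALSE)
  }
}

#' Cross-validate an extraction + selection + LDA configuration
#'
#' Stratified k-fold cross-validation of the full pipeline. Within each fold
#' the extractor (PCA / FastICA / Gabor bank), the greedy basis selection and
#' the Fisher discriminant see only the training portion; the held-out fold
#' is classified and its confusion counts recorded. Reported metrics are
#' unweighted means over folds.
#'
#' @param dataset A [roi_dataset()] with exactly two label values.
#' @param extractor An [extractor_pca()], [extractor_ica()] or
#'   [extractor_gabor()] configuration.
#' @param n_components Number of components/filters used by the classifier.
#' @param k Number of folds (default 10).
#' @param seed RNG seed controlling the fold split and any per-fold fits.
#' @param positive_class Positive ("mass"-like) label; defaulted as in
#'   [lda_fit()].
#' @return An object of class `cad_eval`: `per_fold` (tibble of confusion
#'   counts and metrics per fold), `mean_accuracy`, `mean_sensitivity`,
#'   `mean_specificity`, and `config`.
#' @export
crossvalidate <- function(dataset, extractor, n_components, k = 10L,
                          seed = 1L, positive_class = NULL) {
  stopifnot(inherits(dataset, "roi_dataset"), inherits(extractor, "cad_extractor"))
  classes <- sort(unique(dataset$labels))
  if (length(classes) != 2L) {
    stop("cross-validation requires a binary-labeled dataset", call. = FALSE)
  }
  if (is.null(positive_class)) {
    positive_class <- if ("mass" %in% classes) "mass"
      else if ("malignant" %in% classes) "malignant"
      else classes[1]
  }
  folds <- stratified_kfold(dataset$labels, k, seed)
  per_fold <- purrr::map(seq_len(k), function(f) {
    tr <- which(folds != f); te <- which(folds == f)
    feats <- tryCatch(
      .fold_features(extractor, dataset$data, dataset$labels, tr, te,
                     n_order = n_components, seed = seed + f,
                     positive_class = positive_class),
      error = function(e) stop(sprintf("fold %d: %s", f, conditionMessage(e)),
                               call. = FALSE))
    model <- lda_fit(feats$train, dataset$labels[tr],
                     positive_class = positive_class)
    pred <- lda_predict(model, feats$test)
    cc <- .confusion_counts(dataset$labels[te], pred, positive_class)
    dplyr::bind_cols(tibble::tibble(fold = f, TP = cc$TP, TN = cc$TN,
                                    FP = cc$FP, FN = cc$FN),
                     compute_metrics(cc))
  })
  per_fold <- dplyr::bind_rows(per_fold)
  structure(list(per_fold = per_fold,
                 mean_accuracy = mean(per_fold$accuracy),
                 mean_sensitivity = mean(per_fold$sensitivity),
                 mean_specificity = mean(per_fold$specificity),
                 config = list(method = extractor$kind,
                               n_components = n_components, k = k,
                               seed = seed, positive_class = positive_class)),
            class = "cad_eval")
}

#' @export
print.cad_eval <- function(x, ...) {
  cat(sprintf("<cad_eval> %s, %d components, %d-fold CV (seed %d)\n",
              x$config$method, x$config$n_components, x$config$k, x$config$seed))
  cat(sprintf("  accuracy %.4f | sensitivity %.4f | specificity %.4f\n",
              x$mean_accuracy, x$mean_sensitivity, x$mean_specificity))
  invisible(x)
}

#' Sweep classifier performance over component counts
#'
#' Reruns the cross-validated pipeline for every component count in
#' `component_range`. Within each fold the extractor is fitted once and the
#' greedy selection ordered once up to `max(component_range)`; each count
#' then reuses the corresponding prefix (greedy order is prefix-consistent by
#' construction), so the sweep costs little more than its largest entry.
#'
#' @inheritParams crossvalidate
#' @param component_range Integer vector of component counts to evaluate.
#' @return A tibble of class `cad_sweep` with one row per count:
#'   `method`, `n_components`, `accuracy`, `sensitivity`, `specificity`
#'   (fold means).
#' @export
component_sweep <- function(dataset, extractor, component_range, k = 10L,
                            seed = 1L, positive_class = NULL) {
  stopifnot(inherits(dataset, "roi_dataset"), inherits(extractor, "cad_extractor"))
  component_range <- sort(unique(as.integer(component_range)))
  stopifnot(length(component_range) >= 1L, all(component_range >= 1L))
  classes <- sort(unique(dataset$labels))
  if (length(classes) != 2L) {
    stop("cross-validation requires a binary-labeled dataset", call. = FALSE)
  }
  if (is.null(positive_class)) {
    positive_class <- if ("mass" %in% classes) "mass"
      else if ("malignant" %in% classes) "malignant"
      else classes[1]
  }
  n_max <- max(component_range)
  folds <- stratified_kfold(dataset$labels, k, seed)

  fold_rows <- purrr::map(seq_len(k), function(f) {
    tr <- which(folds != f); te <- which(folds == f)
    feats <- .fold_features(extractor, dataset$data, dataset$labels, tr, te,
                            n_order = n_max, seed = seed + f,
                            positive_class = positive_class)
    avail <- nrow(feats$train)
    purrr::map(component_range[component_range <= avail], function(nc) {
      model <- lda_fit(feats$train[seq_len(nc), , drop = FALSE],
                       dataset$labels[tr], positive_class = positive_class)
      pred <- lda_predict(model, feats$test[seq_len(nc), , drop = FALSE])
      cc <- .confusion_counts(dataset$labels[te], pred, positive_class)
      dplyr::bind_cols(tibble::tibble(fold = f, n_components = nc),
                       compute_metrics(cc))
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()

  out <- fold_rows |>
    dplyr::group_by(.data$n_components) |>
    dplyr::summarise(accuracy = mean(.data$accuracy),
                     sensitivity = mean(.data$sensitivity),
                     specificity = mean(.data$specificity),
                     .groups = "drop") |>
    dplyr::mutate(method = extractor$kind, .before = 1)
  class(out) <- c("cad_sweep", class(out))
  attr(out, "per_fold") <- fold_rows
  attr(out, "config") <- list(method = extractor$kind, k = k, seed = seed)
  out
}
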
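#' ROI image container
#'
#' A single grayscale region of interest (ROI): a rectangular pixel grid with
#' 8-bit intensities and a provenance string. This is the raw unit every
#' preprocessing step operates on.
#'
#' @param pixels Numeric matrix of intensities in `[0, 255]` (rows = image
#'   rows, columns = image columns).
#' @param source_id Provenance string (file path, synthetic tag, ...).
#' @return An object of class `roi_image` with elements `pixels` and
#'   `source_id`.
#' @export
roi_image <- function(pixels, source_id = NA_character_) {
  if (!is.matrix(pixels) || length(pixels) == 0L) {
    stop("`pixels` must be a non-empty matrix", call. = FALSE)
  }
  if (!is.numeric(pixels) || any(!is.finite(pixels))) {
    stop("`pixels` must be finite numeric intensities", call. = FALSE)
  }
  if (min(pixels) < 0 || max(pixels) > 255) {
    stop("intensities must lie in [0, 255]", call. = FALSE)
  }
  structure(list(pixels = pixels, source_id = as.character(source_id)),
            class = "roi_image")
}

#' @export
print.roi_image <- function(x, ...) {
  cat(sprintf("<roi_image> %dx%d, range [%d, %d], source: %s\n",
              nrow(x$pixels), ncol(x$pixels),
              round(min(x$pixels)), round(max(x$pixels)), x$source_id))
  invisible(x)
}

#' ROI dataset container
#'
#' The canonical data matrix: one vectorized (row-concatenated) ROI per
#' column, with aligned class labels and provenance ids.
#'
#' @param data Numeric matrix, one sample vector per column.
#' @param labels Character vector of class labels, one per column.
#' @param ids Character vector of provenance ids, one per column.
#' @param side Side length of the canonical square image (pixels).
#' @return An object of class `roi_dataset`.
#' @export
roi_dataset <- function(data, labels, ids = NULL, side = as.integer(sqrt(nrow(data)))) {
  if (!is.matrix(data) || ncol(data) == 0L) {
    stop("`data` must be a matrix with at least one column", call. = FALSE)
  }
  labels <- as.character(labels)
  if (is.null(ids)) ids <- sprintf("sample-%04d", seq_len(ncol(data)))
  ids <- as.character(ids)
  if (length(labels) != ncol(data) || length(ids) != ncol(data)) {
    stop("`labels` and `ids` must have one entry per data column", call. = FALSE)
  }
  if (nrow(data) != side^2) {
    stop(sprintf("column length %d does not equal side^2 = %d", nrow(data), side^2),
         call. = FALSE)
  }
  structure(list(data = data, labels = labels, ids = ids, side = as.integer(side)),
            class = "roi_dataset")
}

#' @export
print.roi_dataset <- function(x, ...) {
  tab <- table(x$labels)
  cat(sprintf("<roi_dataset> %d samples x %d pixels (%dx%d)\n",
              ncol(x$data), nrow(x$data), x$side, x$side))
  cat("  labels:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.roi_dataset <- function(x) dim(x$data)

# internal: accept a roi_dataset or a bare matrix
.as_data_matrix <- function(x) {
  if (inherits(x, "roi_dataset")) x$data
  else if (is.matrix(x)) x
  else stop("expected a `roi_dataset` or a numeric matrix", call. = FALSE)
}

#' Feature matrix container
#'
#' Projection coefficients of a dataset onto a set of basis functions:
#' one row per basis/component, one column per sample, labels aligned to
#' columns.
#'
#' @param features Numeric matrix of coefficients (components x samples).
#' @param labels Character vector of class labels, one per column (optional).
#' @return An object of class `feature_matrix`.
#' @export
feature_matrix <- function(features, labels = NULL) {
  if (!is.matrix(features)) stop("`features` must be a matrix", call. = FALSE)
  if (!is.null(labels) && length(labels) != ncol(features)) {
    stop("`labels` length must equal the number of samples", call. = FALSE)
  }
  structure(list(features = features,
                 labels = if (is.null(labels)) NULL else as.character(labels)),
            class = "feature_matrix")
}

.as_feature_matrix <- function(x) {
  if (inherits(x, "feature_matrix")) x$features
  else if (is.matrix(x)) x
  else if (is.numeric(x)) matrix(x, nrow = length(x))
  else stop("expected a `feature_matrix` or a numeric matrix", call. = FALSE)
}

#' Basis set container
#'
#' A family of basis functions or filters rendered as vectors on the canonical
#' pixel grid: one column per basis, plus per-column metadata (family, scale /
#' orientation or eigenvalue, selection rank).
#'
#' @param vectors Numeric matrix, one basis vector per column.
#' @param meta A tibble with one row per column of `vectors`.
#' @return An object of class `basis_set`.
#' @export
basis_set <- function(vectors, meta = NULL) {
  if (!is.matrix(vectors) || ncol(vectors) == 0L) {
    stop("`vectors` must be a matrix with at least one column", call. = FALSE)
  }
  if (is.null(meta)) {
    meta <- tibble::tibble(kind = rep(NA_character_, ncol(vectors)))
  }
  if (nrow(meta) != ncol(vectors)) {
    stop("`meta` must have one row per basis vector", call. = FALSE)
  }
  structure(list(vectors = vectors, meta = tibble::as_tibble(meta)),
            class = "basis_set")
}

#' @export
print.basis_set <- function(x, ...) {
  cat(sprintf("<basis_set> %d basis vectors of length %d\n",
              ncol(x$vectors), nrow(x$vectors)))
  if ("kind" %in% names(x$meta)) {
    cat("  kinds:", paste(unique(x$meta$kind), collapse = ", "), "\n")
  }
  invisible(x)
}
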
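#' Histogram equalization of an ROI
#'
#' Standard discrete histogram equalization over 256 gray levels: each level
#' is mapped through the empirical CDF rescaled to `[0, 255]`,
#' `out(v) = round(255 * (cdf(v) - cdf_min) / (N - cdf_min))` with `N` the
#' pixel count and `cdf_min` the CDF at the lowest occupied level. A constant
#' image (degenerate CDF, `cdf_min = N`) is returned unchanged.
#'
#' Equalization spreads each patch's intensities over the full dynamic range,
#' which removes film-exposure differences between ROIs and emphasizes local
#' structure before any basis is learned.
#'
#' @param image A [roi_image()].
#' @return The equalized [roi_image()].
#' @export
equalize_histogram <- function(image) {
  stopifnot(inherits(image, "roi_image"))
  px <- round(image$pixels)
  n <- length(px)
  counts <- tabulate(as.integer(px) + 1L, nbins = 256L)
  cdf <- cumsum(counts)
  cdf_min <- min(cdf[counts > 0L])
  if (cdf_min == n) return(image)          # constant image: identity by convention
  lut <- round(255 * (cdf - cdf_min) / (n - cdf_min))
  out <- matrix(lut[as.integer(px) + 1L], nrow(px), ncol(px))
  roi_image(out, image$source_id)
}

#' Resize an ROI by bilinear interpolation
#'
#' Resamples to a `side` x `side` grid using bilinear interpolation with
#' half-pixel-centered sampling (output pixel centers are mapped uniformly
#' onto input pixel centers). Interpolated intensities stay within the input's
#' `[min, max]`; the result is rounded back to 8-bit levels.
#'
#' @param image A [roi_image()].
#' @param side Output side length in pixels (>= 2).
#' @return The resized [roi_image()].
#' @export
resize_roi <- function(image, side = 32L) {
  stopifnot(inherits(image, "roi_image"))
  side <- as.integer(side)
  if (is.na(side) || side < 2L) stop("`side` must be at least 2", call. = FALSE)
  px <- image$pixels
  h <- nrow(px); w <- ncol(px)
  if (h == side && w == side) return(image)

  # map output pixel centers (1..side) onto input pixel-center coordinates
  src_coord <- function(n_in, n_out) {
    s <- (seq_len(n_out) - 0.5) * n_in / n_out + 0.5
    pmin(pmax(s, 1), n_in)
  }
  ys <- src_coord(h, side); xs <- src_coord(w, side)
  y0 <- pmin(floor(ys), h - 1L); x0 <- pmin(floor(xs), w - 1L)
  if (h == 1L) y0 <- rep(1L, side)
  if (w == 1L) x0 <- rep(1L, side)
  fy <- ys - y0; fx <- xs - x0
  y1 <- pmin(y0 + 1L, h); x1 <- pmin(x0 + 1L, w)

  A <- px[y0, x0, drop = FALSE]; B <- px[y0, x1, drop = FALSE]
  C <- px[y1, x0, drop = FALSE]; D <- px[y1, x1, drop = FALSE]
  out <- outer(1 - fy, 1 - fx) * A + outer(1 - fy, fx) * B +
         outer(fy, 1 - fx) * C + outer(fy, fx) * D
  roi_image(pmin(pmax(round(out), 0), 255), image$source_id)
}

#' Vectorize an ROI by row concatenation
#'
#' Concatenates rows of pixels into a single vector of length `side^2`
#' (row-major order), the sample representation every basis is learned on.
#'
#' @param image A [roi_image()].
#' @return Numeric vector of length `nrow * ncol`.
#' @export
vectorize_roi <- function(image) {
  stopifnot(inherits(image, "roi_image"))
  as.vector(t(image$pixels))
}

#' Build a canonical dataset from raw ROI images
#'
#' Applies the full preprocessing chain — histogram equalization, bilinear
#' resize to `side` x `side`, row-major vectorization — to each image and
#' assembles the column data matrix, preserving order.
#'
#' @param images List of [roi_image()] objects.
#' @param labels Class labels, one per image.
#' @param side Canonical side length (default 32, giving 1024-vectors).
#' @param ids Optional provenance ids (defaults to the images' `source_id`s).
#' @return A [roi_dataset()].
#' @export
build_dataset <- function(images, labels, side = 32L, ids = NULL) {
  if (length(images) == 0L) stop("`images` must contain at least one image", call. = FALSE)
  if (length(images) != length(labels)) {
    stop("`images` and `labels` must have equal length", call. = FALSE)
  }
  cols <- vapply(images, function(im) {
    vectorize_roi(resize_roi(equalize_histogram(im), side))
  }, numeric(side^2))
  if (is.null(ids)) ids <- vapply(images, function(im) im$source_id, character(1))
  roi_dataset(matrix(cols, nrow = side^2), labels, ids, side = side)
}

#' Read a grayscale ROI image from disk
#'
#' Supports PNG and TIFF (via the \pkg{png} / \pkg{tiff} packages) and ASCII
#' or binary PGM. Multi-channel images are converted to grayscale by channel
#' averaging; intensities are rescaled to 8-bit levels.
#'
#' @param path Path to the image file.
#' @return A [roi_image()] with `source_id = path`.
#' @export
read_roi_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    a <- png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      stop("reading TIFF requires the 'tiff' package", call. = FALSE)
    }
    a <- tiff::readTIFF(path)
  } else if (ext == "pgm") {
    return(roi_image(.read_pgm(path), path))
  } else {
    stop(sprintf("unsupported image format '%s' (use png/pgm/tiff)", ext), call. = FALSE)
  }
  if (length(dim(a)) == 3L) a <- apply(a, c(1, 2), mean)
  roi_image(round(a * 255), path)
}

# minimal PGM (P2 ascii / P5 binary) reader; maxval <= 255 assumed
.read_pgm <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  magic <- readLines(con, n = 1L)
  toks <- character(0)
  while (length(toks) < 3L) {
    ln <- readLines(con, n = 1L)
    ln <- sub("#.*$", "", ln)
    toks <- c(toks, strsplit(trimws(ln), "\\s+")[[1]])
    toks <- toks[nzchar(toks)]
  }
  w <- as.integer(toks[1]); h <- as.integer(toks[2]); maxv <- as.integer(toks[3])
  if (maxv > 255L) stop("only 8-bit PGM supported", call. = FALSE)
  if (magic == "P2") {
    vals <- scan(con, what = integer(), n = w * h, quiet = TRUE)
  } else if (magic == "P5") {
    vals <- as.integer(readBin(con, "raw", n = w * h))
  } else {
    stop("not a PGM file", call. = FALSE)
  }
  matrix(vals, nrow = h, ncol = w, byrow = TRUE)
}

#' Write a dataset to disk as PNG files plus a CSV manifest
#'
#' Each column is reshaped back to its square image and written as an 8-bit
#' grayscale PNG; `manifest.csv` records `filename,label,id`. The pair
#' round-trips bit-exactly through [read_roi_dataset()].
#'
#' @param dataset A [roi_dataset()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest tibble.
#' @export
write_roi_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "roi_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  side <- dataset$side
  fnames <- sprintf("roi-%05d.png", seq_len(ncol(dataset$data)))
  for (i in seq_along(fnames)) {
    img <- matrix(dataset$data[, i], side, side, byrow = TRUE)
    png::writePNG(img / 255, file.path(dir, fnames[i]))
  }
  manifest <- tibble::tibble(filename = fnames, label = dataset$labels,
                             id = dataset$ids)
  readr::write_csv(manifest, file.path(dir, "manifest.csv"))
  invisible(manifest)
}

#' Read a dataset written by [write_roi_dataset()]
#'
#' Reads the manifest and PNGs back into a [roi_dataset()] verbatim (no
#' re-preprocessing), so write-then-read is bit-exact. To preprocess raw,
#' unequalized images from a manifest instead, use [read_roi_manifest()] and
#' [build_dataset()].
#'
#' @param dir Directory holding `manifest.csv` and the PNG files.
#' @return A [roi_dataset()].
#' @export
read_roi_dataset <- function(dir) {
  manifest <- readr::read_csv(file.path(dir, "manifest.csv"),
                              show_col_types = FALSE)
  imgs <- lapply(file.path(dir, manifest$filename), read_roi_image)
  side <- nrow(imgs[[1]]$pixels)
  cols <- vapply(imgs, vectorize_roi, numeric(side^2))
  roi_dataset(matrix(cols, nrow = side^2), manifest$label, manifest$id, side = side)
}

#' Read raw ROI images listed in a CSV manifest
#'
#' @param manifest_path Path to a CSV with columns `filename` and `label`
#'   (filenames relative to the manifest's directory).
#' @return A list with `images` (list of [roi_image()]) and `labels`.
#' @export
read_roi_manifest <- function(manifest_path) {
  manifest <- readr::read_csv(manifest_path, show_col_types = FALSE)
  base <- dirname(manifest_path)
  imgs <- lapply(file.path(base, manifest$filename), read_roi_image)
  list(images = imgs, labels = as.character(manifest$label))
}
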
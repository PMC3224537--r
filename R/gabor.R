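#' Parameters of the Gabor filter bank
#'
#' A bank of band-pass, orientation-tuned filters obtained by rotating and
#' scaling a mother Gabor function (Gaussian envelope times a sinusoidal
#' carrier; its Fourier transform is a Gaussian shifted away from DC).
#' Orientation of filter `n` is `theta = n * pi / k`, `n = 0 .. k-1`; scale
#' `m = 1 .. M` shrinks coordinates by `scale_factor^(m-1)`, so `m = 1`
#' carries `base_frequency` exactly and the coarsest scale carries
#' `base_frequency / scale_factor^(M-1)`.
#'
#' Defaults: 10 scales x 10 orientations (a 100-filter bank), frequencies
#' tiling 0.4 down to 0.05 cycles/pixel, and an envelope width giving roughly
#' one octave of frequency bandwidth.
#'
#' @param n_scales Number of scales `M` (default 10).
#' @param n_orientations Number of orientations `k` (default 10).
#' @param base_frequency Carrier frequency at `m = 1`, cycles/pixel.
#' @param scale_factor Ratio between successive scales (> 1). The default
#'   spans 0.4 to 0.05 cycles/pixel across 10 scales.
#' @param sigma_x,sigma_y Envelope standard deviations (pixels) along and
#'   across the carrier at the base scale. Default: ~1-octave bandwidth.
#' @param grid_side Side of the rendering grid (default 32).
#' @return An object of class `gabor_params`.
#' @export
gabor_params <- function(n_scales = 10L, n_orientations = 10L,
                         base_frequency = 0.4,
                         scale_factor = (0.4 / 0.05)^(1 / 9),
                         sigma_x = NULL, sigma_y = NULL,
                         grid_side = 32L) {
  stopifnot(n_scales >= 1, n_orientations >= 1,
            base_frequency > 0, scale_factor > 0, grid_side >= 4)
  if (is.null(sigma_x)) {
    # envelope for ~1 octave half-amplitude frequency bandwidth
    sigma_x <- sqrt(log(2) / 2) * (2^1 + 1) / (pi * base_frequency * (2^1 - 1))
  }
  if (is.null(sigma_y)) sigma_y <- sigma_x
  stopifnot(sigma_x > 0, sigma_y > 0)
  structure(list(n_scales = as.integer(n_scales),
                 n_orientations = as.integer(n_orientations),
                 base_frequency = base_frequency,
                 scale_factor = scale_factor,
                 sigma_x = sigma_x, sigma_y = sigma_y,
                 grid_side = as.integer(grid_side)),
            class = "gabor_params")
}

#' Render one Gabor kernel
#'
#' Real part of the 2-D Gabor function
#' `g(x, y) = (2 pi sx sy)^-1 exp(-(x^2/sx^2 + y^2/sy^2)/2) exp(2 pi i F x)`
#' with coordinates rotated by `theta = n pi / k` and shrunk by
#' `scale_factor^(m-1)`, rendered on the centered `grid_side` grid,
#' DC-corrected to exactly zero mean, and L2-normalized to unit norm.
#'
#' @param m Scale index, `1 <= m <= n_scales`.
#' @param n Orientation index, `0 <= n < n_orientations`.
#' @param params A [gabor_params()] object.
#' @return A `grid_side` x `grid_side` numeric matrix (zero mean, unit norm).
#' @export
gabor_kernel <- function(m, n, params = gabor_params()) {
  stopifnot(inherits(params, "gabor_params"))
  if (m < 1 || m > params$n_scales) {
    stop(sprintf("`m` must be in [1, %d]", params$n_scales), call. = FALSE)
  }
  if (n < 0 || n >= params$n_orientations) {
    stop(sprintf("`n` must be in [0, %d]", params$n_orientations - 1L), call. = FALSE)
  }
  s <- params$grid_side
  theta <- n * pi / params$n_orientations
  a <- params$scale_factor^(-(m - 1))
  cc <- (s + 1) / 2
  y <- matrix(seq_len(s) - cc, s, s)           # rows: vertical coordinate
  x <- matrix(seq_len(s) - cc, s, s, byrow = TRUE)
  xr <- a * (x * cos(theta) + y * sin(theta))
  yr <- a * (-x * sin(theta) + y * cos(theta))
  g <- exp(-0.5 * (xr^2 / params$sigma_x^2 + yr^2 / params$sigma_y^2)) *
    cos(2 * pi * params$base_frequency * xr)
  g <- g - mean(g)
  g / sqrt(sum(g^2))
}

#' Build the full Gabor filter bank
#'
#' Renders all `n_scales * n_orientations` kernels (scale-major order: all
#' orientations of scale 1, then scale 2, ...), each DC-corrected,
#' unit-normalized and row-major vectorized.
#'
#' @param params A [gabor_params()] object.
#' @return A [basis_set()] with one column per filter and metadata columns
#'   `kind`, `scale`, `orientation`, `theta`, `frequency`.
#' @export
gabor_bank <- function(params = gabor_params()) {
  stopifnot(inherits(params, "gabor_params"))
  M <- params$n_scales; k <- params$n_orientations
  p <- params$grid_side^2
  vecs <- matrix(0, p, M * k)
  meta <- vector("list", M * k)
  i <- 0L
  for (m in seq_len(M)) {
    for (n in 0:(k - 1L)) {
      i <- i + 1L
      vecs[, i] <- as.vector(t(gabor_kernel(m, n, params)))
      meta[[i]] <- tibble::tibble(
        kind = "gabor", scale = m, orientation = n,
        theta = n * pi / k,
        frequency = params$base_frequency * params$scale_factor^(-(m - 1)))
    }
  }
  basis_set(vecs, dplyr::bind_rows(meta))
}

#' Project a dataset onto selected Gabor filters
#'
#' Single inner product of each sample vector with each selected filter on
#' the canonical grid (no convolution or pooling), mirroring how PCA and ICA
#' coefficients are formed. Samples are optionally centered by a fixed vector
#' (e.g. the training mean); because every filter is zero-mean, centering by
#' a constant image leaves projections unchanged.
#'
#' @param data A [roi_dataset()] or matrix (samples in columns).
#' @param bank A [gabor_bank()] basis set.
#' @param selected Integer filter indices (1-based); defaults to all.
#' @param center Optional per-pixel centering vector.
#' @return A [feature_matrix()] with `length(selected)` rows, in `selected`
#'   order.
#' @export
gabor_project <- function(data, bank, selected = seq_len(ncol(bank$vectors)),
                          center = NULL) {
  stopifnot(inherits(bank, "basis_set"))
  selected <- as.integer(selected)
  if (any(is.na(selected)) || any(selected < 1L) ||
      any(selected > ncol(bank$vectors))) {
    stop("`selected` contains out-of-range filter indices", call. = FALSE)
  }
  X <- .as_data_matrix(data)
  if (nrow(X) != nrow(bank$vectors)) {
    stop("data dimensionality does not match the filter bank", call. = FALSE)
  }
  if (!is.null(center)) X <- X - center
  feature_matrix(crossprod(bank$vectors[, selected, drop = FALSE], X),
                 if (inherits(data, "roi_dataset")) data$labels else NULL)
}
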
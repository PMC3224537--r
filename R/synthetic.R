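#' Parameters of the synthetic ROI generator
#'
#' Defines the generative law for labeled synthetic ROIs: a stationary
#' correlated-noise texture (Gaussian random field: white noise smoothed by an
#' isotropic Gaussian kernel) for every patch, plus — for mass-like labels —
#' an additive, roughly blob-shaped bright structure with a smooth (benign) or
#' spiculated (malignant) contour.
#'
#' @param image_size Side length in pixels (default 32).
#' @param blob_contrast Relative intensity lift of the mass blob, in
#'   `[0, Inf)`; the blob amplitude is `blob_contrast` times the background
#'   level, so 0 makes mass and non-mass distributions identical.
#' @param blob_radius_range Two-vector, min/max blob radius in pixels.
#' @param texture_correlation_length Gaussian smoothing sigma of the texture
#'   field, in pixels.
#' @param noise_sd Standard deviation of additive white pixel noise
#'   (intensity units).
#' @param malignant_spiculation Contour irregularity factor in `[0, 1]` used
#'   for the `malignant` label (0 gives a smooth contour).
#' @param seed RNG seed; identical parameters (including seed) reproduce a
#'   dataset byte-for-byte.
#' @return An object of class `synth_params`.
#' @export
synth_params <- function(image_size = 32L,
                         blob_contrast = 0.8,
                         blob_radius_range = c(5, 9),
                         texture_correlation_length = 2,
                         noise_sd = 5,
                         malignant_spiculation = 0.6,
                         seed = 1L) {
  stopifnot(image_size >= 8, blob_contrast >= 0,
            length(blob_radius_range) == 2L,
            blob_radius_range[1] > 0,
            blob_radius_range[2] >= blob_radius_range[1],
            texture_correlation_length > 0, noise_sd >= 0,
            malignant_spiculation >= 0, malignant_spiculation <= 1)
  structure(list(image_size = as.integer(image_size),
                 blob_contrast = blob_contrast,
                 blob_radius_range = blob_radius_range,
                 texture_correlation_length = texture_correlation_length,
                 noise_sd = noise_sd,
                 malignant_spiculation = malignant_spiculation,
                 seed = as.integer(seed)),
            class = "synth_params")
}

.synth_labels <- c("mass", "non-mass", "benign", "malignant")

# background level and texture amplitude of the synthetic law (8-bit units)
.SYNTH_BG <- 110
.SYNTH_TEXTURE_SD <- 25

# unit-variance Gaussian random field via separable smoothing of white noise
.correlated_field <- function(s, corr_len) {
  pad <- ceiling(3 * corr_len)
  n <- s + 2L * pad
  g <- stats::dnorm(seq(-pad, pad), sd = corr_len)
  g <- g / sum(g)
  # banded convolution matrix (n x n), edges renormalized implicitly by crop
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - pad); hi <- min(n, i + pad)
    K[i, lo:hi] <- g[(lo:hi) - i + pad + 1L]
  }
  w <- matrix(stats::rnorm(n * n), n, n)
  sm <- K %*% w %*% t(K)
  core <- sm[(pad + 1L):(pad + s), (pad + 1L):(pad + s)]
  core / sum(g^2)  # Var(smoothed) = (sum g^2)^2 for the separable kernel
}

#' Generate a single synthetic ROI
#'
#' Draws one labeled patch from the generative law in [synth_params()], using
#' the current RNG stream. `non-mass` patches are texture only; `mass` and
#' `benign` add a smooth-contoured blob; `malignant` adds a spiculated blob
#' with extra contrast variance. Intensities are clipped to `[0, 255]` and
#' rounded to 8-bit levels.
#'
#' @param label One of `"mass"`, `"non-mass"`, `"benign"`, `"malignant"`.
#' @param params A [synth_params()] object.
#' @return A [roi_image()].
#' @export
generate_roi <- function(label, params = synth_params()) {
  stopifnot(inherits(params, "synth_params"))
  if (!is.character(label) || length(label) != 1L || !(label %in% .synth_labels)) {
    stop(sprintf("unknown label '%s' (expected one of: %s)",
                 as.character(label)[1], paste(.synth_labels, collapse = ", ")),
         call. = FALSE)
  }
  s <- params$image_size
  img <- .SYNTH_BG +
    .SYNTH_TEXTURE_SD * .correlated_field(s, params$texture_correlation_length) +
    matrix(stats::rnorm(s * s, sd = params$noise_sd), s, s)

  if (label != "non-mass") {
    img <- img + .blob_lift(label, params)
  }
  roi_image(pmin(pmax(round(img), 0), 255), sprintf("synthetic-%s", label))
}

# additive blob: sigmoid-edged disc whose radius may be modulated over angle
.blob_lift <- function(label, params) {
  s <- params$image_size
  ctr <- (s + 1) / 2
  cy <- ctr + stats::runif(1, -2, 2)
  cx <- ctr + stats::runif(1, -2, 2)
  r0 <- stats::runif(1, params$blob_radius_range[1], params$blob_radius_range[2])
  amp <- params$blob_contrast * .SYNTH_BG
  spic <- if (label == "malignant") params$malignant_spiculation else 0
  if (label == "malignant") amp <- amp * exp(stats::rnorm(1, 0, 0.25))

  yy <- matrix(seq_len(s), s, s) - cy
  xx <- matrix(seq_len(s), s, s, byrow = TRUE) - cx
  d <- sqrt(yy^2 + xx^2)
  rad <- r0
  # margin sharpness doubles as a shape cue: spiculated lesions get an
  # ill-defined, sharper-edged margin than the smooth benign sigmoid
  edge <- 1.6 - 0.9 * spic
  if (spic > 0) {
    # angular radius modulation: a few random sinusoidal lobes
    harm <- sample(4:9, 3L, replace = TRUE)
    a <- stats::runif(3); a <- a / sum(a)
    ph <- stats::runif(3, 0, 2 * pi)
    th <- atan2(yy, xx)
    mod <- a[1] * cos(harm[1] * th + ph[1]) + a[2] * cos(harm[2] * th + ph[2]) +
      a[3] * cos(harm[3] * th + ph[3])
    rad <- r0 * (1 + 0.5 * spic * mod)
  }
  amp / (1 + exp((d - rad) / edge))
}

#' Generate a labeled synthetic ROI dataset
#'
#' Generates exactly the requested number of ROIs per label, shuffles the
#' column order deterministically, and pushes every image through the standard
#' preprocessing chain ([build_dataset()]: equalize, resize, vectorize) so the
#' result is a canonical [roi_dataset()].
#'
#' @param n_per_class Named vector of non-negative counts, e.g.
#'   `c(mass = 3240, "non-mass" = 1850)`.
#' @param params A [synth_params()] object; `params$seed` fixes the dataset.
#' @return A [roi_dataset()] with `sum(n_per_class)` columns.
#' @examples
#' d <- generate_dataset(c(mass = 10, "non-mass" = 10),
#'                       synth_params(seed = 7))
#' table(d$labels)
#' @export
generate_dataset <- function(n_per_class, params = synth_params()) {
  stopifnot(inherits(params, "synth_params"))
  if (is.null(names(n_per_class)) || any(!nzchar(names(n_per_class)))) {
    stop("`n_per_class` must be a named vector of counts", call. = FALSE)
  }
  if (any(n_per_class < 0)) stop("counts must be non-negative", call. = FALSE)
  bad <- setdiff(names(n_per_class), .synth_labels)
  if (length(bad)) {
    stop(sprintf("unknown label '%s'", bad[1]), call. = FALSE)
  }
  n_per_class <- n_per_class[n_per_class > 0]
  if (length(n_per_class) == 0L) stop("requested an empty dataset", call. = FALSE)

  old_seed <- .save_rng()
  on.exit(.restore_rng(old_seed))
  set.seed(params$seed)

  labels <- rep(names(n_per_class), times = n_per_class)
  imgs <- lapply(labels, generate_roi, params = params)
  ord <- sample.int(length(labels))
  ids <- sprintf("synth-%05d", seq_along(labels))
  build_dataset(imgs[ord], labels[ord], side = params$image_size, ids = ids)
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
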
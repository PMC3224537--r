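#' Run a full, reproducible classification experiment
#'
#' Glue around the whole pipeline: load or simulate a dataset, cross-validate
#' the chosen extraction method, and persist the results (JSON report,
#' per-fold CSV, the resolved config, and optionally a basis-montage PNG) so
#' a run can be re-executed bit-for-bit from its config file. This is the
#' function behind the command-line entry point in
#' `system.file("cli", "mammicad.R", package = "mammicad")`.
#'
#' @param config A named list, or a path to a YAML/JSON config file, with
#'   fields:
#'   \describe{
#'     \item{method}{`"pca"`, `"ica"` or `"gabor"`.}
#'     \item{components}{Number of components/filters (default 39 for PCA,
#'       41 otherwise).}
#'     \item{folds}{CV folds (default 10).}
#'     \item{seed}{Integer seed (default 1).}
#'     \item{data}{Either `list(synthetic = list(mass = ..., "non-mass" = ...,
#'       blob_contrast = ..., ...))` (counts per label plus optional
#'       [synth_params()] overrides) or `list(dir = "path")` pointing at a
#'       dataset written by [write_roi_dataset()].}
#'     \item{output_dir}{Directory for artifacts (created; default `NULL`
#'       writes nothing).}
#'     \item{sweep}{Optional integer vector of component counts; when given,
#'       a [component_sweep()] table is computed and written as CSV.}
#'     \item{write_plots}{Write a basis-montage PNG (default `FALSE`).}
#'   }
#' @return The [crossvalidate()] report (invisibly also written to disk when
#'   `output_dir` is set), with the sweep table attached as
#'   `attr(, "sweep")` when requested.
#' @export
run_experiment <- function(config) {
  cfg <- .load_config(config)
  method <- cfg$method
  if (is.null(method) || !is.character(method) ||
      !(method %in% c("pca", "ica", "gabor"))) {
    stop(sprintf("unknown `method` '%s' (expected pca, ica or gabor)",
                 if (is.null(method)) "<missing>" else as.character(method)[1]),
         call. = FALSE)
  }
  seed <- as.integer(cfg$seed %||% 1L)
  folds <- as.integer(cfg$folds %||% 10L)
  components <- as.integer(cfg$components %||% if (method == "pca") 39L else 41L)

  dataset <- .load_experiment_data(cfg$data, seed)
  extractor <- switch(method,
    pca = extractor_pca(),
    ica = extractor_ica(n_candidates = cfg$n_candidates),
    gabor = extractor_gabor())

  message(sprintf("[mammicad] %s | %d samples | %d components | %d-fold CV | seed %d",
                  method, ncol(dataset$data), components, folds, seed))
  t0 <- Sys.time()
  report <- crossvalidate(dataset, extractor, components, k = folds, seed = seed)
  message(sprintf("[mammicad] CV done in %.1fs: accuracy %.4f",
                  as.numeric(difftime(Sys.time(), t0, units = "secs")),
                  report$mean_accuracy))

  sweep_tab <- NULL
  if (!is.null(cfg$sweep)) {
    sweep_tab <- component_sweep(dataset, extractor, as.integer(unlist(cfg$sweep)),
                                 k = folds, seed = seed)
    attr(report, "sweep") <- sweep_tab
  }

  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(
      list(config = report$config,
           mean_accuracy = report$mean_accuracy,
           mean_sensitivity = report$mean_sensitivity,
           mean_specificity = report$mean_specificity),
      file.path(cfg$output_dir, "report.json"),
      auto_unbox = TRUE, digits = NA)
    readr::write_csv(report$per_fold, file.path(cfg$output_dir, "per_fold.csv"))
    jsonlite::write_json(cfg, file.path(cfg$output_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
    if (!is.null(sweep_tab)) {
      readr::write_csv(tibble::as_tibble(sweep_tab),
                       file.path(cfg$output_dir, "sweep.csv"))
    }
    if (isTRUE(cfg$write_plots)) {
      .write_basis_montage(method, dataset, extractor, cfg$output_dir, seed)
    }
  }
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.load_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop(sprintf("config file '%s' not found", config),
                                   call. = FALSE)
    ext <- tolower(tools::file_ext(config))
    config <- if (ext %in% c("yml", "yaml")) yaml::read_yaml(config)
              else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!is.list(config)) stop("`config` must be a list or a config-file path",
                             call. = FALSE)
  config
}

.load_experiment_data <- function(data_cfg, seed) {
  if (is.null(data_cfg)) stop("config field `data` is required", call. = FALSE)
  if (!is.null(data_cfg$synthetic)) {
    sp <- data_cfg$synthetic
    counts <- unlist(sp[intersect(names(sp), .synth_labels)])
    if (length(counts) == 0L) {
      stop("`data$synthetic` must name per-label counts", call. = FALSE)
    }
    par_names <- intersect(names(sp), names(formals(synth_params)))
    pars <- sp[par_names]
    pars$seed <- as.integer(sp$seed %||% seed)
    generate_dataset(counts, do.call(synth_params, pars))
  } else if (!is.null(data_cfg$dir)) {
    read_roi_dataset(data_cfg$dir)
  } else {
    stop("config field `data` must contain `synthetic` or `dir`", call. = FALSE)
  }
}

.write_basis_montage <- function(method, dataset, extractor, out_dir, seed) {
  plt <- switch(method,
    pca = autoplot(pca_fit(dataset), n = 25L),
    gabor = autoplot(extractor$bank, n = 25L),
    ica = {
      wh <- whiten(dataset, extractor$var_floor, max_rank = extractor$n_candidates)
      nc <- min(wh$model$retained_rank, 25L)
      autoplot(fastica_fit(wh, nc, max_iter = extractor$max_iter,
                           tol = extractor$tol, seed = seed), n = 25L)
    })
  ggplot2::ggsave(file.path(out_dir, sprintf("basis-%s.png", method)),
                  plt, width = 6, height = 6, dpi = 120)
  invisible(NULL)
}
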
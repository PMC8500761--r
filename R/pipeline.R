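# Orchestration: configuration, end-to-end segmentation, the threshold-ratio
# sweep experiment, and the held-out phantom benchmark.

#' Pipeline configuration
#'
#' One master seed derives deterministic substreams for every stage
#' (phantom geometry/noise, swarm, fold assignment), so any run is
#' reproducible from its config alone.
#'
#' @param canny a [canny_params()].
#' @param window feature-extraction window (odd, >= 3).
#' @param folds cross-validation folds for hyperparameter tuning.
#' @param swarm optional [swarm_config()] for the tuner (a small
#'   decaying-inertia swarm is built from the seed when `NULL`).
#' @param phantom named list of [default_wrist_spec()] overrides
#'   (`width`, `height`, `noise_sigma`, `bias_amplitude`, `contrast`).
#' @param max_per_class cap on training edge pixels per class (subsampled
#'   deterministically) to bound solver cost.
#' @param close_size closing-brush side for lesion-mask reconstruction.
#' @param seed master integer seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(canny = canny_params(sigma = 1.5, t_l = 0.02,
                                                 ratio = 1.8),
                            window = 5L, folds = 3L, swarm = NULL,
                            phantom = list(), max_per_class = 300L,
                            close_size = 5L, seed = 1L) {
  if (!inherits(canny, "canny_params")) abort("`canny` must be canny_params.")
  structure(list(canny = canny, window = as.integer(window),
                 folds = as.integer(folds), swarm = swarm,
                 phantom = phantom, max_per_class = as.integer(max_per_class),
                 close_size = as.integer(close_size), seed = as.integer(seed)),
            class = "pipeline_config")
}

config_phantom_spec <- function(config, seed) {
  do.call(default_wrist_spec, c(list(seed = seed), config$phantom))
}

#' Segment an image with a trained model
#'
#' Runs the full inference chain: Canny detection, per-edge-pixel feature
#' extraction, SVM classification of edge pixels, and lesion-mask
#' reconstruction. Deterministic for a fixed config.
#'
#' @param img numeric image matrix in `[0, 1]`, or a path readable by
#'   [read_image()].
#' @param model a trained [svm_train()] model (or path to a JSON model
#'   written by [write_svm_model()]).
#' @param config a [pipeline_config()].
#' @return A list: `lesion_mask`, `lesion_edges`, `edges`, and `record`
#'   (one-row tibble of stage timings and counts).
#' @export
run_segmentation <- function(img, model, config = pipeline_config()) {
  if (is.character(img)) img <- read_image(img)
  if (is.character(model)) model <- read_svm_model(model)
  check_image(img)
  t0 <- proc.time()[["elapsed"]]
  smoothed <- gaussian_smooth(img, config$canny$sigma)
  field <- compute_gradient(smoothed)
  nms <- nonmax_suppress(field)
  t_l <- if (config$canny$relative) config$canny$t_l * max(nms) else config$canny$t_l
  edges <- if (t_l <= 0) matrix(0, nrow(img), ncol(img)) else
    hysteresis_link(nms, t_l, max(config$canny$ratio * t_l, t_l))
  t1 <- proc.time()[["elapsed"]]
  cls <- classify_edges(img, edges, field, model, window = config$window,
                        close_size = config$close_size)
  t2 <- proc.time()[["elapsed"]]
  record <- tibble::tibble(
    n_edge_pixels = sum(edges), n_lesion_edges = sum(cls$lesion_edges),
    n_mask_pixels = sum(cls$lesion_mask),
    t_detect = t1 - t0, t_classify = t2 - t1, seed = config$seed)
  list(lesion_mask = cls$lesion_mask, lesion_edges = cls$lesion_edges,
       edges = edges, record = record)
}

#' Threshold-ratio sweep
#'
#' Detects edges at a fixed low threshold while sweeping the high/low
#' threshold ratio, and scores each edge map for continuity and (when
#' ground truth is available) credibility. Ratios at or below 1 collapse to
#' a single threshold at `t_l`.
#'
#' @param x a `wrist_phantom`, an image matrix, or an image path.
#' @param ratios numeric vector of `t_h / t_l` ratios.
#' @param config a [pipeline_config()]; its `canny` block supplies `sigma`
#'   and `t_l`.
#' @param truth_edges optional binary truth edge map (taken from the phantom
#'   automatically).
#' @return Tibble with one row per ratio: `ratio`, `n_edge_pixels`, `ci`,
#'   `bi` (`NA` without truth).
#' @export
sweep_ratio <- function(x, ratios = c(0.3, 0.6, 0.9, 1.2, 1.5, 1.8),
                        config = pipeline_config(), truth_edges = NULL) {
  if (any(ratios <= 0)) abort("All `ratios` must be > 0.")
  if (inherits(x, "wrist_phantom")) {
    truth_edges <- x$truth_edges
    img <- x$image
  } else if (is.character(x)) {
    img <- read_image(x)
  } else {
    img <- x
  }
  check_image(img)
  smoothed <- gaussian_smooth(img, config$canny$sigma)
  nms <- nonmax_suppress(compute_gradient(smoothed))
  t_l <- if (config$canny$relative) config$canny$t_l * max(nms) else config$canny$t_l
  purrr::map_dfr(ratios, function(r) {
    edges <- hysteresis_link(nms, t_l, max(r * t_l, t_l))
    tibble::tibble(
      ratio = r,
      n_edge_pixels = sum(edges),
      ci = edge_continuity(edges),
      bi = if (is.null(truth_edges)) NA_real_ else
        edge_credibility(edges, truth_edges))
  })
}

# Pooled, labelled, per-class-capped training features from a set of phantoms.
collect_training_features <- function(phantoms, config) {
  feats <- purrr::map_dfr(phantoms, function(ph) {
    smoothed <- gaussian_smooth(ph$image, config$canny$sigma)
    field <- compute_gradient(smoothed)
    nms <- nonmax_suppress(field)
    t_l <- if (config$canny$relative) config$canny$t_l * max(nms) else config$canny$t_l
    edges <- hysteresis_link(nms, t_l, max(config$canny$ratio * t_l, t_l))
    extract_edge_features(ph$image, edges, field, window = config$window) |>
      label_edge_pixels(ph$lesion_mask)
  })
  withr::with_seed(derive_seed(config$seed, "subsample"), {
    feats |>
      dplyr::group_by(.data$label) |>
      dplyr::slice_sample(n = config$max_per_class) |>
      dplyr::ungroup()
  })
}

#' Train a lesion-edge classifier on a set of phantoms
#'
#' Pools labelled edge features from the phantoms, caps each class,
#' PSO-tunes `(C, gamma)` by cross-validation and trains the final RBF SVM.
#'
#' @param phantoms list of `wrist_phantom`s.
#' @param config a [pipeline_config()].
#' @return List: `model` ([svm_train()] fit), `tuning` ([pso_svm_tune()]
#'   result), `n_train` (training rows used).
#' @export
train_lesion_classifier <- function(phantoms, config = pipeline_config()) {
  train <- collect_training_features(phantoms, config)
  if (length(unique(train$label)) < 2) {
    abort("Training phantoms produced edge pixels of only one class.")
  }
  x <- as.matrix(train[, feature_cols])
  tuning <- pso_svm_tune(x, train$label, folds = config$folds,
                         config = config$swarm,
                         seed = derive_seed(config$seed, "tune"))
  model <- svm_train(x, train$label, C = tuning$C,
                     kernel = kernel_spec("rbf", gamma = tuning$gamma),
                     tol = 1e-6, max_iter = 200000L)
  list(model = model, tuning = tuning, n_train = nrow(train))
}

#' Held-out phantom benchmark
#'
#' Generates `n` seeded phantoms, trains the PSO-SVM lesion classifier on
#' the first `n_train` of them, segments the held-out phantoms, and scores
#' every run with the full quality battery. The reference image for
#' PSNR/MSE/SSIM is the noise-free, bias-free rendering of the same
#' geometry; the processed image is the Gaussian-smoothed noisy phantom.
#'
#' @param n total number of phantoms, >= 2.
#' @param config a [pipeline_config()]; `config$seed` derives all phantom
#'   seeds.
#' @param n_train number of phantoms used for training (default half).
#' @return A `benchmark_result`: `per_phantom` (one scored row per held-out
#'   phantom), `summary` (mean and SD per metric), `tuning`, `model`,
#'   `config`.
#' @export
run_benchmark <- function(n = 10L, config = pipeline_config(),
                          n_train = max(1L, n %/% 2L)) {
  if (n < 2) abort("`n` must be >= 2.")
  if (n_train < 1 || n_train >= n) abort("`n_train` must be in [1, n).")
  seeds <- vapply(seq_len(n), function(i) derive_seed(config$seed, paste0("phantom", i)),
                  integer(1))
  phantoms <- lapply(seeds, function(s) generate_phantom(config_phantom_spec(config, s)))
  fit <- train_lesion_classifier(phantoms[seq_len(n_train)], config)
  test_idx <- (n_train + 1L):n
  per <- purrr::map_dfr(test_idx, function(i) {
    ph <- phantoms[[i]]
    noisefree_spec <- config_phantom_spec(config, seeds[i])
    noisefree_spec$noise_sigma <- 0
    noisefree_spec$bias_amplitude <- 0
    reference <- generate_phantom(noisefree_spec)$image
    seg <- run_segmentation(ph$image, fit$model, config)
    processed <- gaussian_smooth(ph$image, config$canny$sigma)
    quality_report(reference, processed, seg$edges, ph$truth_edges,
                   seg$lesion_mask, ph$lesion_mask) |>
      dplyr::mutate(phantom = i, seed = seeds[i], .before = 1)
  })
  metrics <- c("psnr", "mse", "fom", "ssim", "ci", "bi",
               "accuracy", "sensitivity", "specificity", "dice")
  summary <- per |>
    tidyr::pivot_longer(dplyr::all_of(metrics), names_to = "metric") |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(mean = mean(.data$value), sd = sd(.data$value),
                     .groups = "drop") |>
    dplyr::arrange(match(.data$metric, metrics))
  structure(list(per_phantom = per, summary = summary,
                 tuning = fit$tuning, model = fit$model,
                 n = n, n_train = n_train, config = config),
            class = "benchmark_result")
}
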
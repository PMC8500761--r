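# Kernel SVM: dual trained by the compiled SMO solver, plus edge-pixel
# feature extraction, PSO hyperparameter tuning, and edge classification.

#' Kernel specification
#'
#' @param kind `"rbf"` (default, `exp(-gamma ||a - b||^2)`) or `"linear"`.
#' @param gamma RBF width parameter, > 0; ignored for the linear kernel.
#' @return A `kernel_spec` list.
#' @export
kernel_spec <- function(kind = c("rbf", "linear"), gamma = 1) {
  kind <- match.arg(kind)
  if (kind == "rbf" && gamma <= 0) abort("`gamma` must be > 0 for the RBF kernel.")
  structure(list(kind = kind, gamma = gamma), class = "kernel_spec")
}

kernel_matrix <- function(kernel, a, b = a) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (kernel$kind == "linear") return(tcrossprod(a, b))
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  exp(-kernel$gamma * pmax(d2, 0))
}

# Dual objective U(alpha) = sum(alpha) - 0.5 alpha' Q alpha, Q = yy' * K.
dual_objective <- function(alpha, K, y) {
  sum(alpha) - 0.5 * drop(crossprod(alpha * y, K %*% (alpha * y)))
}

#' Train a soft-margin kernel SVM
#'
#' Maximizes the dual `U(k) = sum_i k_i - 0.5 sum_is k_i k_s g_i g_s
#' K(a_i, a_s)` subject to `sum_i k_i g_i = 0` and `0 <= k_i <= C`, by an
#' SMO-style maximal-violating-pair solver. The offset is the average of
#' `g_i - sum_s k_s g_s K(a_s, a_i)` over free (unbounded) support vectors.
#'
#' @param x numeric matrix (or data frame) of feature vectors, one row per
#'   sample.
#' @param y labels in `{-1, +1}`; both classes must be present.
#' @param C soft-margin penalty, > 0.
#' @param kernel a [kernel_spec()].
#' @param tol KKT violation tolerance for the solver stopping rule.
#' @param max_iter pair-update budget.
#' @return An `svm_model`: `alpha` (all multipliers), `b` (offset), `sv`
#'   (support-vector rows), `sv_alpha`, `sv_y`, `weights` (linear kernel
#'   only), `kernel`, `C`, solver diagnostics.
#' @examples
#' x <- rbind(c(0, 0), c(2, 0))
#' m <- svm_train(x, c(-1, 1), C = 1e6, kernel = kernel_spec("linear"))
#' m$weights  # (1, 0): hyperplane x1 = 1
#' @export
svm_train <- function(x, y, C = 1, kernel = kernel_spec(), tol = 1e-8,
                      max_iter = 200000L) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as.numeric(y)
  if (nrow(x) != length(y)) abort("`x` rows and `y` length must match.")
  if (nrow(x) < 2) abort("Need at least two training samples.")
  if (!all(y %in% c(-1, 1))) abort("Labels must be -1 or +1.")
  if (length(unique(y)) < 2) abort("Both classes must be present for training.")
  if (C <= 0) abort("`C` must be > 0.")
  if (!inherits(kernel, "kernel_spec")) abort("`kernel` must be a kernel_spec.")
  K <- kernel_matrix(kernel, x)
  fit <- smo_solve(K, y, C, tol, as.integer(max_iter))
  if (!fit$converged && fit$max_violation > 1e-3) {
    abort(sprintf(
      "SMO solver did not converge: %d iterations, max KKT violation %.3g.",
      fit$iterations, fit$max_violation))
  }
  alpha <- fit$alpha
  sv_idx <- which(alpha > 1e-10)
  weights <- if (kernel$kind == "linear") {
    drop(crossprod(x, alpha * y))
  } else NULL
  structure(list(alpha = alpha, b = fit$b,
                 sv = x[sv_idx, , drop = FALSE],
                 sv_alpha = alpha[sv_idx], sv_y = y[sv_idx],
                 sv_index = sv_idx, weights = weights,
                 kernel = kernel, C = C,
                 iterations = fit$iterations,
                 max_violation = fit$max_violation,
                 dual_value = dual_objective(alpha, K, y),
                 n_features = ncol(x), n_samples = nrow(x)),
            class = "svm_model")
}

#' Kernel decision values
#'
#' `f(a) = sum_i k_i g_i K(a_i, a) + b`, summed over support vectors.
#'
#' @param model an [svm_train()] fit.
#' @param newx matrix of points, one per row (dimension must match training).
#' @return Numeric vector of decision values.
#' @export
svm_decision <- function(model, newx) {
  if (!inherits(model, "svm_model")) abort("`model` must be an svm_model.")
  newx <- as.matrix(newx)
  if (ncol(newx) != model$n_features) {
    abort(sprintf("Point dimension %d does not match training dimension %d.",
                  ncol(newx), model$n_features))
  }
  if (nrow(model$sv) == 0) return(rep(model$b, nrow(newx)))
  Kp <- kernel_matrix(model$kernel, newx, model$sv)
  drop(Kp %*% (model$sv_alpha * model$sv_y)) + model$b
}

#' Predict class labels
#'
#' `sgn(f(a))` with the convention `sgn(0) = +1`.
#'
#' @inheritParams svm_decision
#' @return Vector of labels in `{-1, +1}`.
#' @export
svm_predict <- function(model, newx) {
  ifelse(svm_decision(model, newx) >= 0, 1, -1)
}

#' Per-edge-pixel feature vectors
#'
#' One 7-component descriptor per edge pixel: windowed local mean and
#' standard deviation of the image, gradient magnitude, cos/sin of the
#' gradient direction, and the normalized (row, col) position. Windows are
#' reflect-padded at borders.
#'
#' @param img numeric image matrix.
#' @param edges binary edge map (from [canny_detect()]).
#' @param field [compute_gradient()] result for `img` (typically of the
#'   smoothed image used for detection).
#' @param window odd window side length >= 3.
#' @return A tibble with columns `row`, `col`, `local_mean`, `local_sd`,
#'   `grad_mag`, `cos_theta`, `sin_theta`, `row_norm`, `col_norm`; zero rows
#'   if the edge map is empty.
#' @export
extract_edge_features <- function(img, edges, field, window = 5L) {
  check_image(img)
  check_binary(edges, "edges")
  check_same_dim(img, edges, c("img", "edges"))
  if (window %% 2 == 0 || window < 3) abort("`window` must be odd and >= 3.")
  idx <- which(edges != 0, arr.ind = TRUE)
  empty <- tibble::tibble(row = integer(), col = integer(),
                          local_mean = numeric(), local_sd = numeric(),
                          grad_mag = numeric(), cos_theta = numeric(),
                          sin_theta = numeric(), row_norm = numeric(),
                          col_norm = numeric())
  if (nrow(idx) == 0) return(empty)
  r <- (window - 1L) %/% 2L
  padded <- pad_reflect(img, r)
  h <- nrow(img); w <- ncol(img)
  n <- nrow(idx)
  lm <- numeric(n); ls <- numeric(n)
  for (k in seq_len(n)) {
    patch <- padded[idx[k, 1] + 0:(2 * r), idx[k, 2] + 0:(2 * r)]
    lm[k] <- mean(patch)
    ls[k] <- sd(patch)
  }
  theta <- field$direction[idx]
  tibble::tibble(row = as.integer(idx[, 1]), col = as.integer(idx[, 2]),
                 local_mean = lm, local_sd = ls,
                 grad_mag = field$magnitude[idx],
                 cos_theta = cos(theta), sin_theta = sin(theta),
                 row_norm = if (h > 1) unname((idx[, 1] - 1) / (h - 1)) else rep(0, n),
                 col_norm = if (w > 1) unname((idx[, 2] - 1) / (w - 1)) else rep(0, n))
}

feature_cols <- c("local_mean", "local_sd", "grad_mag", "cos_theta",
                  "sin_theta", "row_norm", "col_norm")

#' Label edge pixels against a ground-truth lesion mask
#'
#' An edge pixel is lesion-positive iff it lies within Chebyshev distance 1
#' of the boundary of the truth lesion mask.
#'
#' @param features an [extract_edge_features()] tibble.
#' @param lesion_mask binary ground-truth lesion mask.
#' @return The tibble with a `label` column in `{-1, +1}` appended.
#' @export
label_edge_pixels <- function(features, lesion_mask) {
  check_binary(lesion_mask, "lesion_mask")
  boundary <- label_boundary(as_binary(lesion_mask)) * as_binary(lesion_mask)
  near <- dilate_square(boundary, 1)
  lab <- ifelse(near[cbind(features$row, features$col)] > 0, 1, -1)
  dplyr::mutate(features, label = lab)
}

#' Tune SVM hyperparameters by particle swarm
#'
#' PSO minimizes `1 - k`-fold cross-validated accuracy over
#' `log10(C) in [-2, 4]` and `log10(gamma) in [-4, 2]` (RBF kernel).
#' Fold assignment is stratified by class and fixed by the seed, so the
#' whole search is deterministic.
#'
#' @param x feature matrix (or tibble of feature columns).
#' @param y labels in `{-1, +1}`; at least `folds` samples per class.
#' @param folds number of cross-validation folds.
#' @param config a [swarm_config()] with `dims = 2`; defaults to a small
#'   decaying-inertia swarm.
#' @param seed seed for the fold assignment (and the default swarm).
#' @return A `svm_tuning` list: `C`, `gamma`, `cv_accuracy`, `pso`
#'   (the [pso_minimize()] result), `folds`.
#' @export
pso_svm_tune <- function(x, y, folds = 3L, config = NULL, seed = 1L) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  if (min(table(y)) < folds) abort("Need at least `folds` samples per class.")
  if (is.null(config)) {
    config <- swarm_config(n_particles = 10, dims = 2,
                           lower = c(-2, -4), upper = c(4, 2),
                           c1 = 1.5, c2 = 1.5,
                           inertia = 0.9, inertia_end = 0.4,
                           max_iters = 12, seed = derive_seed(seed, "swarm"))
  }
  if (config$dims != 2) abort("Tuning searches (log10 C, log10 gamma): dims must be 2.")
  fold_id <- withr::with_seed(derive_seed(seed, "folds"), {
    id <- integer(length(y))
    for (cl in c(-1, 1)) {
      members <- which(y == cl)
      id[members] <- sample(rep_len(seq_len(folds), length(members)))
    }
    id
  })
  cv_error <- function(par) {
    C <- 10^par[1]; gamma <- 10^par[2]
    correct <- 0L
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      m <- svm_train(x[tr, , drop = FALSE], y[tr], C = C,
                     kernel = kernel_spec("rbf", gamma = gamma),
                     tol = 1e-6, max_iter = 50000L)
      correct <- correct + sum(svm_predict(m, x[!tr, , drop = FALSE]) == y[!tr])
    }
    1 - correct / length(y)
  }
  res <- pso_minimize(cv_error, config)
  structure(list(C = 10^res$par[1], gamma = 10^res$par[2],
                 cv_accuracy = 1 - res$value, pso = res, folds = folds),
            class = "svm_tuning")
}

#' Classify detected edges and reconstruct the lesion mask
#'
#' Predicts lesion membership for every detected edge pixel with a trained
#' model, then turns the positive edge subset into a filled region by 3x3
#' (configurable) morphological closing followed by hole filling.
#'
#' @param img image matrix the edges came from.
#' @param edges binary edge map.
#' @param field gradient field used for the features.
#' @param model trained [svm_train()] model.
#' @param window feature window (must match training).
#' @param close_size side of the square closing brush, odd; bridges small
#'   gaps in the predicted lesion contour before filling.
#' @return List with `lesion_edges` (binary matrix of positive edge pixels)
#'   and `lesion_mask` (filled binary matrix).
#' @export
classify_edges <- function(img, edges, field, model, window = 5L,
                           close_size = 5L) {
  if (!inherits(model, "svm_model")) abort("`model` must be a trained svm_model.")
  features <- extract_edge_features(img, edges, field, window = window)
  lesion_edges <- matrix(0, nrow(img), ncol(img))
  if (nrow(features) > 0) {
    pred <- svm_predict(model, as.matrix(features[, feature_cols]))
    pos <- features[pred > 0, ]
    lesion_edges[cbind(pos$row, pos$col)] <- 1
  }
  mask <- lesion_edges
  if (any(mask > 0)) {
    brush <- EBImage::makeBrush(as.integer(close_size), shape = "box")
    mask <- EBImage::closing(mask, brush)
    mask <- EBImage::fillHull(mask)
    mask <- as_binary(matrix(as.numeric(mask), nrow(img), ncol(img)))
  }
  list(lesion_edges = lesion_edges, lesion_mask = mask)
}
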
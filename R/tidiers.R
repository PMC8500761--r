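# broom-style tidiers and ggplot2 autoplot methods.

#' @export
tidy.svm_model <- function(x, ...) {
  tibble::tibble(sv = x$sv_index, alpha = x$sv_alpha, label = x$sv_y,
                 bounded = x$sv_alpha >= x$C - 1e-10)
}

#' @export
glance.svm_model <- function(x, ...) {
  tibble::tibble(n_samples = x$n_samples, n_features = x$n_features,
                 n_sv = length(x$sv_alpha), C = x$C,
                 kernel = x$kernel$kind,
                 gamma = if (x$kernel$kind == "rbf") x$kernel$gamma else NA_real_,
                 offset = x$b, dual_value = x$dual_value %||% NA_real_,
                 iterations = x$iterations %||% NA_integer_)
}

#' @export
tidy.pso_result <- function(x, ...) {
  tibble::tibble(iteration = seq_along(x$history) - 1L, gbest = x$history)
}

#' @export
glance.pso_result <- function(x, ...) {
  tibble::tibble(value = x$value, n_particles = x$config$n_particles,
                 dims = x$config$dims, iterations = x$config$max_iters,
                 n_evals = x$n_evals)
}

#' @export
tidy.svm_tuning <- function(x, ...) tidy(x$pso)

#' @export
glance.svm_tuning <- function(x, ...) {
  tibble::tibble(C = x$C, gamma = x$gamma, cv_accuracy = x$cv_accuracy,
                 folds = x$folds)
}

#' @export
tidy.benchmark_result <- function(x, ...) x$summary

#' @export
glance.benchmark_result <- function(x, ...) {
  wide <- setNames(as.list(x$summary$mean), x$summary$metric)
  dplyr::bind_cols(tibble::tibble(n = x$n, n_train = x$n_train),
                   tibble::as_tibble(wide))
}

raster_df <- function(m) {
  tibble::tibble(
    row = rep(seq_len(nrow(m)), times = ncol(m)),
    col = rep(seq_len(ncol(m)), each = nrow(m)),
    value = as.vector(m))
}

#' Plot an image matrix
#'
#' @param img numeric matrix in `[0, 1]`.
#' @param title optional plot title.
#' @return A ggplot.
#' @export
plot_image <- function(img, title = NULL) {
  df <- raster_df(img)
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white", limits = c(0, 1)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = title, x = NULL, y = NULL, fill = "intensity") +
    ggplot2::theme_minimal()
}

#' Overlay an edge map on an image
#'
#' @param img numeric background image.
#' @param edges binary edge map.
#' @param color edge overlay color.
#' @return A ggplot.
#' @export
plot_edges <- function(img, edges, color = "red") {
  pts <- which(edges != 0, arr.ind = TRUE)
  plot_image(img) +
    ggplot2::geom_point(
      data = tibble::tibble(row = pts[, 1], col = pts[, 2]),
      ggplot2::aes(.data$col, .data$row), inherit.aes = FALSE,
      color = color, size = 0.3)
}

#' @export
autoplot.wrist_phantom <- function(object, what = c("image", "truth_edges",
                                                    "lesion_mask", "label"),
                                   ...) {
  what <- match.arg(what)
  if (what == "truth_edges") return(plot_edges(object$image, object$truth_edges))
  m <- object[[what]]
  if (what == "label") m <- m / max(max(m), 1)
  plot_image(m, title = what)
}

#' @export
autoplot.pso_result <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(.data$iteration, .data$gbest)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "iteration", y = "global best fitness") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.benchmark_result <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(.data$metric, .data$mean)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           width = 0.25) +
    ggplot2::labs(x = NULL, y = "mean ± SD across held-out phantoms") +
    ggplot2::theme_minimal()
}

`%||%` <- function(a, b) if (is.null(a)) b else a
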
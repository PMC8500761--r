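# Canny edge detection: Gaussian smoothing, gradient field, non-maximum
# suppression, double-threshold hysteresis linking.

#' Truncated, renormalized 2-D Gaussian kernel
#'
#' Isotropic Gaussian `exp(-(x^2 + y^2) / (2 sigma^2)) / (2 pi sigma^2)`,
#' truncated at `radius` pixels and renormalized so the weights sum to 1.
#'
#' @param sigma Gaussian width in pixels, > 0.
#' @param radius truncation radius in pixels; default `ceiling(3 * sigma)`.
#' @return A `(2 radius + 1)` square matrix of weights summing to 1.
#' @export
gaussian_kernel <- function(sigma, radius = ceiling(3 * sigma)) {
  if (sigma <= 0) abort("`sigma` must be > 0.")
  x <- seq.int(-radius, radius)
  g <- exp(-x^2 / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

#' Smooth an image with a Gaussian kernel
#'
#' Convolution with a truncated, renormalized Gaussian; borders are handled
#' by symmetric reflection so constant images are preserved exactly.
#'
#' @param img numeric matrix, intensities in `[0, 1]`.
#' @param sigma Gaussian width in pixels, > 0.
#' @param radius truncation radius; default `ceiling(3 * sigma)`.
#' @return Smoothed matrix, same dimensions as `img`.
#' @export
gaussian_smooth <- function(img, sigma, radius = ceiling(3 * sigma)) {
  check_image(img)
  if (sigma <= 0) abort("`sigma` must be > 0.")
  # separable: convolve rows then columns with the 1-D profile
  x <- seq.int(-radius, radius)
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  padded <- pad_reflect(img, radius)
  h <- nrow(img); w <- ncol(img)
  tmp <- matrix(0, h, ncol(padded))
  for (k in seq_along(g)) {
    tmp <- tmp + g[k] * padded[seq_len(h) + (k - 1L), , drop = FALSE]
  }
  out <- matrix(0, h, w)
  for (k in seq_along(g)) {
    out <- out + g[k] * tmp[, seq_len(w) + (k - 1L), drop = FALSE]
  }
  out
}

#' Gradient field of an image
#'
#' Finite-difference partial derivatives (central differences in the
#' interior, one-sided at the borders), with gradient magnitude
#' `D = sqrt(gx^2 + gy^2)` and direction `theta = atan2(gy, gx)`.
#' `x` runs along columns and `y` along rows.
#'
#' @param img numeric matrix, at least 3x3.
#' @return A `gradient_field` list with matrices `gx`, `gy`, `magnitude`,
#'   `direction` (radians in `(-pi, pi]`).
#' @export
compute_gradient <- function(img) {
  check_image(img)
  h <- nrow(img); w <- ncol(img)
  if (h < 3 || w < 3) abort("Image must be at least 3x3 for gradients.")
  gx <- matrix(0, h, w)
  gx[, 2:(w - 1)] <- (img[, 3:w] - img[, 1:(w - 2)]) / 2
  gx[, 1] <- img[, 2] - img[, 1]
  gx[, w] <- img[, w] - img[, w - 1]
  gy <- matrix(0, h, w)
  gy[2:(h - 1), ] <- (img[3:h, ] - img[1:(h - 2), ]) / 2
  gy[1, ] <- img[2, ] - img[1, ]
  gy[h, ] <- img[h, ] - img[h - 1, ]
  structure(list(gx = gx, gy = gy,
                 magnitude = sqrt(gx^2 + gy^2),
                 direction = atan2(gy, gx)),
            class = "gradient_field")
}

#' Non-maximum suppression
#'
#' Thins the gradient magnitude to candidate one-pixel-wide ridges: a pixel
#' keeps its magnitude only if it is strictly greater than both neighbors
#' along the gradient direction (quantized to 4 sectors: 0, 45, 90, 135
#' degrees; no sub-pixel interpolation). Neighbors outside the image count
#' as zero. Constant fields are suppressed entirely by the strict rule.
#'
#' @param field a [compute_gradient()] result.
#' @return Matrix of suppressed magnitudes (zero off-ridge).
#' @export
nonmax_suppress <- function(field) {
  if (!inherits(field, "gradient_field")) abort("`field` must be a gradient_field.")
  d <- field$magnitude
  # sector of the gradient direction, modulo pi
  ang <- field$direction %% pi
  sector <- ifelse(ang < pi / 8, 0L,
            ifelse(ang < 3 * pi / 8, 1L,
            ifelse(ang < 5 * pi / 8, 2L,
            ifelse(ang < 7 * pi / 8, 3L, 0L))))
  # neighbor offsets along the gradient direction per sector
  # sector 0: gradient ~ along x (columns); 2: along y (rows); 1/3 diagonals.
  # direction (gy, gx): sector 1 ~ 45deg => neighbor (dr, dc) = (1, 1)
  nb <- list(`0` = c(0L, 1L), `1` = c(1L, 1L), `2` = c(1L, 0L), `3` = c(1L, -1L))
  out <- matrix(0, nrow(d), ncol(d))
  for (s in 0:3) {
    off <- nb[[as.character(s)]]
    n1 <- shift_mat(d, off[1], off[2], fill = 0)
    n2 <- shift_mat(d, -off[1], -off[2], fill = 0)
    keep <- sector == s & d > n1 & d > n2
    out[keep] <- d[keep]
  }
  out
}

#' Double-threshold hysteresis edge linking
#'
#' Pixels at or above `t_h` are strong edges; pixels in `[t_l, t_h)` are weak
#' and kept only if 8-connected to a strong pixel through weak or strong
#' pixels; pixels below `t_l` are never edges.
#'
#' @param nms suppressed-magnitude matrix from [nonmax_suppress()].
#' @param t_l,t_h low and high thresholds, `0 < t_l <= t_h`.
#' @return Binary edge matrix.
#' @export
hysteresis_link <- function(nms, t_l, t_h) {
  check_image(nms, "nms")
  if (t_l <= 0) abort("`t_l` must be > 0.")
  if (t_l > t_h) abort("`t_l` must be <= `t_h`.")
  strong <- nms >= t_h
  cand <- nms >= t_l          # weak or strong
  edges <- strong
  repeat {
    grown <- cand & (dilate_square(edges, 1) > 0)
    if (identical(grown, edges)) break
    edges <- grown
  }
  edges * 1
}

#' Canny detector parameters
#'
#' @param sigma Gaussian smoothing width in pixels.
#' @param t_l low threshold on the suppressed gradient magnitude. When
#'   `relative = TRUE` it is interpreted as a fraction of the maximum
#'   suppressed magnitude (useful when the absolute gradient scale of an
#'   image is unknown).
#' @param ratio high/low threshold ratio `t_h = ratio * t_l`. Ratios at or
#'   below 1 collapse the double threshold to a single threshold at `t_l`.
#' @param relative interpret `t_l` as a fraction of `max(nms)`.
#' @return A `canny_params` list.
#' @export
canny_params <- function(sigma = 1.5, t_l = 0.04, ratio = 1.8,
                         relative = FALSE) {
  if (sigma <= 0) abort("`sigma` must be > 0.")
  if (t_l <= 0) abort("`t_l` must be > 0.")
  if (ratio <= 0) abort("`ratio` must be > 0.")
  structure(list(sigma = sigma, t_l = t_l, ratio = ratio, relative = relative),
            class = "canny_params")
}

#' Canny edge detection
#'
#' Composition of Gaussian smoothing, gradient computation, non-maximum
#' suppression and double-threshold hysteresis with `t_h = ratio * t_l`.
#' Deterministic.
#'
#' @param img numeric matrix in `[0, 1]`.
#' @param params a [canny_params()].
#' @return Binary edge matrix.
#' @examples
#' ph <- generate_phantom(default_wrist_spec(seed = 1))
#' edges <- canny_detect(ph$image, canny_params(sigma = 1.5, t_l = 0.02))
#' sum(edges)
#' @export
canny_detect <- function(img, params = canny_params()) {
  if (!inherits(params, "canny_params")) abort("`params` must be canny_params.")
  smoothed <- gaussian_smooth(img, params$sigma)
  field <- compute_gradient(smoothed)
  nms <- nonmax_suppress(field)
  t_l <- if (params$relative) params$t_l * max(nms) else params$t_l
  if (t_l <= 0) return(matrix(0, nrow(img), ncol(img)))
  t_h <- max(params$ratio * t_l, t_l)
  hysteresis_link(nms, t_l, t_h)
}
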
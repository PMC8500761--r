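# Segmentation quality battery: PSNR, MSE, Pratt FOM, SSIM, edge continuity
# and credibility indices, confusion counts and diagnostic scores.

#' Mean square error between two images
#'
#' @param reference,test numeric matrices of identical dimensions.
#' @return Mean over pixels of the squared difference.
#' @export
img_mse <- function(reference, test) {
  check_image(reference, "reference"); check_image(test, "test")
  check_same_dim(reference, test)
  mean((reference - test)^2)
}

#' Peak signal-to-noise ratio
#'
#' `10 log10(pe_max^2 / MSE)`; `Inf` when the images are identical.
#'
#' @inheritParams img_mse
#' @param pe_max peak intensity value (1 for images normalized to `[0, 1]`).
#' @return PSNR in dB.
#' @export
img_psnr <- function(reference, test, pe_max = 1) {
  if (pe_max <= 0) abort("`pe_max` must be > 0.")
  m <- img_mse(reference, test)
  if (m == 0) return(Inf)
  10 * log10(pe_max^2 / m)
}

#' Pratt figure of merit for edge maps
#'
#' `FOM = 1 / max(X_det, X_ideal) * sum_det 1 / (1 + rho d^2)` where `d` is
#' the Euclidean distance from each detected edge point to the nearest ideal
#' edge point.
#'
#' @param detected,ideal binary edge matrices of identical dimensions;
#'   `ideal` must be non-empty.
#' @param rho displacement scaling constant (1/9, the conventional value).
#' @return FOM in `[0, 1]`.
#' @export
img_fom <- function(detected, ideal, rho = 1 / 9) {
  check_binary(detected, "detected"); check_binary(ideal, "ideal")
  check_same_dim(detected, ideal, c("detected", "ideal"))
  ideal_pts <- which(ideal != 0, arr.ind = TRUE)
  if (nrow(ideal_pts) == 0) abort("`ideal` edge map must be non-empty.")
  det_pts <- which(detected != 0, arr.ind = TRUE)
  if (nrow(det_pts) == 0) return(0)
  d2 <- nearest_sqdist(det_pts, ideal_pts)
  sum(1 / (1 + rho * d2)) / max(nrow(det_pts), nrow(ideal_pts))
}

# Squared Euclidean distance from each point in `a` to its nearest point in
# `b` (both k x 2 index matrices), chunked to bound memory.
nearest_sqdist <- function(a, b, chunk = 2048L) {
  out <- numeric(nrow(a))
  for (start in seq(1L, nrow(a), by = chunk)) {
    rows <- start:min(start + chunk - 1L, nrow(a))
    dr <- outer(a[rows, 1], b[, 1], "-")
    dc <- outer(a[rows, 2], b[, 2], "-")
    out[rows] <- apply(dr * dr + dc * dc, 1, min)
  }
  out
}

#' Structural similarity index
#'
#' Mean over sliding windows of the brightness x contrast x structure
#' product with unit exponents, stabilizing constants `(0.01 L)^2` and
#' `(0.03 L)^2` (`C3 = C2 / 2`), uniform square windows of side
#' `window` and unit stride.
#'
#' @inheritParams img_mse
#' @param window window side in pixels (both image dimensions must be at
#'   least this large).
#' @param L dynamic range of the intensities (1 for `[0, 1]` images).
#' @return SSIM in `[-1, 1]`.
#' @export
img_ssim <- function(reference, test, window = 8L, L = 1) {
  check_image(reference, "reference"); check_image(test, "test")
  check_same_dim(reference, test)
  h <- nrow(reference); w <- ncol(reference)
  if (h < window || w < window) abort("Images smaller than the SSIM window.")
  C1 <- (0.01 * L)^2; C2 <- (0.03 * L)^2; C3 <- C2 / 2
  # box-filter moments via cumulative sums (integral images)
  box <- function(m) {
    cs <- apply(apply(m, 2, cumsum), 1, cumsum)  # transposed integral image
    cs <- t(cs)
    padded <- matrix(0, h + 1, w + 1)
    padded[2:(h + 1), 2:(w + 1)] <- cs
    i <- seq_len(h - window + 1); j <- seq_len(w - window + 1)
    padded[i + window, j + window, drop = FALSE] -
      padded[i, j + window, drop = FALSE] -
      padded[i + window, j, drop = FALSE] + padded[i, j, drop = FALSE]
  }
  n <- window^2
  mx <- box(reference) / n
  my <- box(test) / n
  vx <- pmax(box(reference^2) / n - mx^2, 0)
  vy <- pmax(box(test^2) / n - my^2, 0)
  cxy <- box(reference * test) / n - mx * my
  sx <- sqrt(vx); sy <- sqrt(vy)
  bri <- (2 * mx * my + C1) / (mx^2 + my^2 + C1)
  con <- (2 * sx * sy + C2) / (vx + vy + C2)
  str <- (cxy + C3) / (sx * sy + C3)
  mean(bri * con * str)
}

edge_segments <- function(edges) {
  pts <- which(edges != 0, arr.ind = TRUE)
  n <- nrow(pts)
  if (n == 0) return(list(pts = pts, membership = integer(0)))
  key <- (pts[, 1] - 1) * (max(pts[, 2]) + 2) + pts[, 2]
  lookup <- seq_len(n)
  names(lookup) <- key
  from <- integer(0); to <- integer(0)
  for (off in list(c(0, 1), c(1, -1), c(1, 0), c(1, 1))) {
    nb_key <- (pts[, 1] + off[1] - 1) * (max(pts[, 2]) + 2) + pts[, 2] + off[2]
    hit <- lookup[as.character(nb_key)]
    ok <- !is.na(hit)
    from <- c(from, which(ok)); to <- c(to, hit[ok])
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = from, to = to), directed = FALSE,
    vertices = data.frame(name = seq_len(n)))
  comp <- igraph::components(g)
  list(pts = pts, membership = comp$membership)
}

#' Edge continuity index
#'
#' Edge segments are 8-connected components of the edge map. For segment `i`
#' with `n_i` pixels, `SE_i` is the fraction of its pixels having at least
#' two 8-neighbors inside the segment (interior pixels of a curve; endpoints
#' and isolated pixels count against continuity). The index is the
#' size-weighted mean `sum n_i SE_i / sum n_i`, capped just below 1 so the
#' value lies in `[0, 1)`: perfectly closed curves approach but never reach
#' 1.
#'
#' @param edges binary edge matrix.
#' @return Continuity index in `[0, 1)`; 0 for an empty map.
#' @export
edge_continuity <- function(edges) {
  check_binary(edges, "edges")
  seg <- edge_segments(edges)
  if (nrow(seg$pts) == 0) return(0)
  deg <- neighbor_count8(as_binary(edges))[seg$pts]
  # neighbors of an edge pixel are necessarily in its own component
  good <- tapply(deg >= 2, seg$membership, mean)
  sizes <- tabulate(seg$membership)
  ci <- sum(sizes * good) / sum(sizes)
  min(ci, 1 - 1e-9)
}

#' Edge credibility index
#'
#' Fraction of detected edge pixels lying within Chebyshev distance 1 of a
#' ground-truth edge pixel.
#'
#' @param detected,truth binary edge matrices of identical dimensions.
#' @return Credibility in `[0, 1]`; 0 for an empty detected map.
#' @export
edge_credibility <- function(detected, truth) {
  check_binary(detected, "detected"); check_binary(truth, "truth")
  check_same_dim(detected, truth, c("detected", "truth"))
  n <- sum(detected != 0)
  if (n == 0) return(0)
  near <- dilate_square(as_binary(truth), 1)
  sum(detected != 0 & near > 0) / n
}

#' Pixelwise confusion counts
#'
#' @param pred,truth binary masks of identical dimensions.
#' @return A `confusion_counts` list with fields `tp`, `tn`, `fp`, `fn`.
#' @export
confusion <- function(pred, truth) {
  check_binary(pred, "pred"); check_binary(truth, "truth")
  check_same_dim(pred, truth, c("pred", "truth"))
  p <- pred != 0; t <- truth != 0
  structure(list(tp = sum(p & t), tn = sum(!p & !t),
                 fp = sum(p & !t), fn = sum(!p & t)),
            class = "confusion_counts")
}

#' Diagnostic scores from confusion counts
#'
#' Accuracy `(TP + TN) / total`, sensitivity `TP / (TP + FN)`, specificity
#' `TN / (TN + FP)` and Dice similarity coefficient
#' `2 TP / (2 TP + FN + FP)`. A score whose denominator is zero is `NA`.
#'
#' @param counts a [confusion()] result (or list with `tp`, `tn`, `fp`,
#'   `fn`).
#' @return One-row tibble with columns `accuracy`, `sensitivity`,
#'   `specificity`, `dice`.
#' @export
diagnostic_scores <- function(counts) {
  tp <- counts$tp; tn <- counts$tn; fp <- counts$fp; fn <- counts$fn
  if (any(c(tp, tn, fp, fn) < 0)) abort("Confusion counts must be >= 0.")
  safe <- function(num, den) if (den > 0) num / den else NA_real_
  tibble::tibble(
    accuracy = safe(tp + tn, tp + tn + fp + fn),
    sensitivity = safe(tp, tp + fn),
    specificity = safe(tn, tn + fp),
    dice = safe(2 * tp, 2 * tp + fn + fp))
}

#' Full quality report for one segmentation run
#'
#' Bundles the image-quality metrics (reference vs processed image), the
#' edge metrics (detected vs truth edges) and the diagnostic scores
#' (predicted vs truth lesion mask) into one row.
#'
#' @param reference noise-free reference image.
#' @param processed processed (e.g. smoothed) image compared against it.
#' @param detected_edges,truth_edges binary edge maps.
#' @param pred_mask,truth_mask binary lesion masks.
#' @return One-row tibble: `psnr`, `mse`, `fom`, `ssim`, `ci`, `bi`,
#'   `accuracy`, `sensitivity`, `specificity`, `dice`.
#' @export
quality_report <- function(reference, processed, detected_edges, truth_edges,
                           pred_mask, truth_mask) {
  scores <- diagnostic_scores(confusion(pred_mask, truth_mask))
  tibble::tibble(
    psnr = img_psnr(reference, processed),
    mse = img_mse(reference, processed),
    fom = img_fom(detected_edges, truth_edges),
    ssim = img_ssim(reference, processed),
    ci = edge_continuity(detected_edges),
    bi = edge_credibility(detected_edges, truth_edges)) |>
    dplyr::bind_cols(scores)
}
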
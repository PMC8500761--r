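#' Describe one phantom region
#'
#' Regions are piecewise-constant shapes painted into the phantom in list
#' order (later regions overwrite earlier ones). Two shapes are supported:
#' `"ellipse"` and `"crescent"` (an ellipse minus a shifted, scaled copy of
#' itself, giving the thin curved sliver typical of carpal cartilage).
#'
#' @param shape `"ellipse"` or `"crescent"`.
#' @param center numeric length-2, (row, col) of the shape center in pixels
#'   (1-based, origin top-left, pixel centers at integer coordinates).
#' @param axes numeric length-2, semi-axes in pixels along (row, col) before
#'   rotation; both must be > 0.
#' @param mean mean intensity of the region, in `[0, 1]`.
#' @param rotation rotation angle in radians (counter-clockwise).
#' @param inner_scale crescent only: scale factor of the subtracted inner
#'   ellipse relative to `axes`.
#' @param inner_shift crescent only: (row, col) shift in pixels of the
#'   subtracted inner ellipse.
#' @return A `region` list usable in [phantom_spec()].
#' @export
region <- function(shape = c("ellipse", "crescent"), center, axes, mean,
                   rotation = 0, inner_scale = 0.85, inner_shift = c(0, 0)) {
  shape <- match.arg(shape)
  if (length(center) != 2 || length(axes) != 2) {
    abort("`center` and `axes` must each have length 2.")
  }
  if (any(axes <= 0)) abort("Degenerate region: both semi-axes must be > 0.")
  if (mean < 0 || mean > 1) abort("Region `mean` must lie in [0, 1].")
  structure(list(shape = shape, center = as.numeric(center),
                 axes = as.numeric(axes), mean = as.numeric(mean),
                 rotation = as.numeric(rotation),
                 inner_scale = as.numeric(inner_scale),
                 inner_shift = as.numeric(inner_shift)),
            class = "wrist_region")
}

#' Specify a synthetic wrist phantom
#'
#' A phantom is a piecewise-near-constant image: a background plus a list of
#' painted regions, modulated by a smooth multiplicative bias field (MRI gray
#' unevenness) and corrupted by additive noise. One region is designated the
#' lesion; its mask and the region-boundary edge map are returned as exact
#' ground truth.
#'
#' @param width,height image size in pixels.
#' @param regions list of [region()] objects, painted in order.
#' @param lesion integer index into `regions` of the lesion region.
#' @param background background intensity in `[0, 1]`.
#' @param bias_amplitude multiplicative bias-field strength `A >= 0`; the
#'   field is a second-order 2-D polynomial rescaled to `[1 - A, 1 + A]`.
#' @param noise_sigma additive noise standard deviation, intensity units.
#' @param noise_model `"gaussian"` (default) or `"rician"`.
#' @param seed integer RNG seed; the phantom is deterministic given the spec.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(width, height, regions, lesion,
                         background = 0.1, bias_amplitude = 0,
                         noise_sigma = 0, noise_model = c("gaussian", "rician"),
                         seed = 1L) {
  noise_model <- match.arg(noise_model)
  if (width < 8 || height < 8) abort("Phantom must be at least 8x8 pixels.")
  if (!length(regions)) abort("`regions` must contain at least one region.")
  for (rg in regions) {
    if (!inherits(rg, "wrist_region")) abort("All regions must be created with region().")
  }
  if (lesion < 1 || lesion > length(regions)) {
    abort("`lesion` must index an existing region.")
  }
  if (noise_sigma < 0) abort("`noise_sigma` must be >= 0.")
  if (bias_amplitude < 0) abort("`bias_amplitude` must be >= 0.")
  if (background < 0 || background > 1) abort("`background` must lie in [0, 1].")
  structure(list(width = as.integer(width), height = as.integer(height),
                 regions = regions, lesion = as.integer(lesion),
                 background = background, bias_amplitude = bias_amplitude,
                 noise_sigma = noise_sigma, noise_model = noise_model,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

ellipse_mask <- function(h, w, center, axes, rotation) {
  rr <- matrix(seq_len(h), h, w) - center[1]
  cc <- matrix(seq_len(w), h, w, byrow = TRUE) - center[2]
  ct <- cos(rotation); st <- sin(rotation)
  u <- ct * rr + st * cc
  v <- -st * rr + ct * cc
  (u / axes[1])^2 + (v / axes[2])^2 <= 1
}

region_mask <- function(rg, h, w) {
  outer <- ellipse_mask(h, w, rg$center, rg$axes, rg$rotation)
  if (rg$shape == "ellipse") return(outer)
  inner <- ellipse_mask(h, w, rg$center + rg$inner_shift,
                        rg$axes * rg$inner_scale, rg$rotation)
  outer & !inner
}

bias_field <- function(h, w, amplitude, seed) {
  if (amplitude == 0) return(matrix(1, h, w))
  coef <- withr::with_seed(derive_seed(seed, "bias"), runif(5, -1, 1))
  xn <- matrix(seq_len(w), h, w, byrow = TRUE) / w * 2 - 1
  yn <- matrix(seq_len(h), h, w) / h * 2 - 1
  f <- coef[1] * xn + coef[2] * yn + coef[3] * xn^2 + coef[4] * yn^2 +
    coef[5] * xn * yn
  rng <- range(f)
  if (diff(rng) < 1e-12) return(matrix(1, h, w))
  1 - amplitude + (f - rng[1]) / diff(rng) * 2 * amplitude
}

label_boundary <- function(label) {
  h <- nrow(label); w <- ncol(label)
  edge <- matrix(FALSE, h, w)
  edge[-h, ] <- edge[-h, ] | label[-h, ] != label[-1, ]
  edge[-1, ] <- edge[-1, ] | label[-1, ] != label[-h, ]
  edge[, -w] <- edge[, -w] | label[, -w] != label[, -1]
  edge[, -1] <- edge[, -1] | label[, -1] != label[, -w]
  edge * 1
}

#' Generate a phantom from its specification
#'
#' Rasterizes the regions (pixel-center point-in-shape tests, painter's
#' order), applies the multiplicative bias field and additive noise, clips to
#' `[0, 1]`, and derives exact ground truth from the noiseless label image:
#' `truth_edges` marks every pixel whose region label differs from at least
#' one 4-neighbor; `lesion_mask` marks the lesion region.
#'
#' @param spec a [phantom_spec()].
#' @return A `wrist_phantom` list: `image` (numeric matrix in `[0, 1]`),
#'   `truth_edges` and `lesion_mask` (binary matrices), `label` (integer
#'   region-label matrix, 0 = background) and `spec`.
#' @examples
#' ph <- generate_phantom(default_wrist_spec(seed = 1))
#' dim(ph$image)
#' @export
generate_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) abort("`spec` must be a phantom_spec.")
  h <- spec$height; w <- spec$width
  label <- matrix(0L, h, w)
  means <- matrix(spec$background, h, w)
  for (k in seq_along(spec$regions)) {
    rg <- spec$regions[[k]]
    m <- region_mask(rg, h, w)
    label[m] <- k
    means[m] <- rg$mean
  }
  img <- means * bias_field(h, w, spec$bias_amplitude, spec$seed)
  if (spec$noise_sigma > 0) {
    img <- withr::with_seed(derive_seed(spec$seed, "noise"), {
      if (spec$noise_model == "gaussian") {
        img + matrix(rnorm(h * w, 0, spec$noise_sigma), h, w)
      } else {
        sqrt((img + matrix(rnorm(h * w, 0, spec$noise_sigma), h, w))^2 +
               matrix(rnorm(h * w, 0, spec$noise_sigma), h, w)^2)
      }
    })
  }
  img <- pmin(pmax(img, 0), 1)
  structure(list(image = img,
                 truth_edges = label_boundary(label),
                 lesion_mask = (label == spec$lesion) * 1,
                 label = label,
                 spec = spec),
            class = "wrist_phantom")
}

#' Default wrist-like phantom specification
#'
#' Emulates the salient difficulties of a coronal wrist MRI slice: several
#' convex bone cross-sections (radius, scaphoid, lunate) with deliberately
#' similar gray levels, a thin crescent of cartilage, a brighter lesion inside
#' one bone, smooth gray unevenness and additive noise. Geometry is jittered
#' slightly by the seed so distinct seeds give distinct but comparable
#' phantoms.
#'
#' @param seed integer seed; controls geometry jitter, bias field and noise.
#' @param width,height image size in pixels.
#' @param noise_sigma additive noise SD (intensity units).
#' @param bias_amplitude multiplicative bias-field strength.
#' @param contrast lesion mean-intensity offset above its host bone.
#' @return A [phantom_spec()].
#' @export
default_wrist_spec <- function(seed = 1L, width = 128L, height = 128L,
                               noise_sigma = 0.03, bias_amplitude = 0.1,
                               contrast = 0.25) {
  sx <- width / 128; sy <- height / 128
  jit <- withr::with_seed(derive_seed(seed, "geometry"), runif(12, -1, 1))
  radius_center <- c(94 * sy + 2 * jit[1], 62 * sx + 2 * jit[2])
  regions <- list(
    # radius: large bone at the bottom of the field of view
    region("ellipse", center = radius_center,
           axes = c(24 * sy + jit[3], 34 * sx + jit[4]),
           mean = 0.58, rotation = 0.15 + 0.05 * jit[5]),
    # scaphoid and lunate: small carpal bones, gray-matched to the radius
    region("ellipse", center = c(44 * sy + 2 * jit[6], 40 * sx + 2 * jit[7]),
           axes = c(13 * sy, 11 * sx), mean = 0.62, rotation = -0.3),
    region("ellipse", center = c(42 * sy + 2 * jit[8], 86 * sx + 2 * jit[9]),
           axes = c(12 * sy, 12 * sx), mean = 0.55, rotation = 0.2),
    # thin crescent of cartilage between radius and carpals
    region("crescent", center = c(62 * sy + jit[10], 63 * sx),
           axes = c(14 * sy, 36 * sx), mean = 0.50,
           inner_scale = 0.80, inner_shift = c(-3.5 * sy, 0)),
    # lesion: focal bright area inside the radius (edema-like on STIR)
    region("ellipse",
           center = radius_center + c(4 * sy + jit[11], 14 * sx + jit[12]),
           axes = c(9 * sy, 7 * sx), mean = min(0.58 + contrast, 1),
           rotation = 0.1)
  )
  phantom_spec(width = width, height = height, regions = regions,
               lesion = 5L, background = 0.12,
               bias_amplitude = bias_amplitude, noise_sigma = noise_sigma,
               seed = seed)
}
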
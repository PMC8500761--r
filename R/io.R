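# Raster, model and config I/O.

#' Read a grayscale image
#'
#' Reads a PNG (8- or 16-bit) or TIFF, converts to grayscale by channel
#' averaging if needed, and returns intensities in `[0, 1]`.
#'
#' @param path PNG or TIFF file path.
#' @return Numeric matrix in `[0, 1]`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) abort(sprintf("Image not found: %s", path))
  arr <- if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    tiff::readTIFF(path)
  } else {
    png::readPNG(path)
  }
  if (length(dim(arr)) == 3) arr <- apply(arr[, , 1:min(3, dim(arr)[3])], c(1, 2), mean)
  arr
}

#' Write a grayscale image
#'
#' `.tif`/`.tiff` paths are written as 16-bit grayscale TIFF (precision
#' preserving); `.png` paths as 8-bit grayscale PNG.
#'
#' @param img numeric matrix; values are clipped to `[0, 1]`.
#' @param path output path.
#' @export
write_image <- function(img, path) {
  check_image(img)
  img <- pmin(pmax(img, 0), 1)
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    tiff::writeTIFF(img, path, bits.per.sample = 16L)
  } else {
    png::writePNG(img, path)
  }
  invisible(path)
}

#' Write a phantom and its ground truth to a directory
#'
#' Writes `image.tif` (16-bit), `truth_edges.png`, `lesion_mask.png` and the
#' generating spec as `spec.yaml`.
#'
#' @param phantom a [generate_phantom()] result.
#' @param dir output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  if (!inherits(phantom, "wrist_phantom")) abort("`phantom` must be a wrist_phantom.")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_image(phantom$image, file.path(dir, "image.tif"))
  write_image(phantom$truth_edges, file.path(dir, "truth_edges.png"))
  write_image(phantom$lesion_mask, file.path(dir, "lesion_mask.png"))
  spec <- phantom$spec
  spec$regions <- lapply(spec$regions, unclass)
  yaml::write_yaml(unclass(spec), file.path(dir, "spec.yaml"))
  invisible(dir)
}

#' Read a phantom spec from YAML
#'
#' Round-trips the block written by [write_phantom()].
#'
#' @param path YAML file path.
#' @return A [phantom_spec()].
#' @export
read_phantom_spec <- function(path) {
  raw <- yaml::read_yaml(path)
  regions <- lapply(raw$regions, function(rg) {
    region(shape = rg$shape, center = unlist(rg$center), axes = unlist(rg$axes),
           mean = rg$mean, rotation = rg$rotation,
           inner_scale = rg$inner_scale, inner_shift = unlist(rg$inner_shift))
  })
  phantom_spec(width = raw$width, height = raw$height, regions = regions,
               lesion = raw$lesion, background = raw$background,
               bias_amplitude = raw$bias_amplitude,
               noise_sigma = raw$noise_sigma, noise_model = raw$noise_model,
               seed = raw$seed)
}

#' Serialize a trained SVM model to JSON
#'
#' @param model an [svm_train()] fit.
#' @param path output JSON path.
#' @export
write_svm_model <- function(model, path) {
  if (!inherits(model, "svm_model")) abort("`model` must be an svm_model.")
  obj <- list(kernel = unclass(model$kernel), C = model$C, b = model$b,
              sv = unname(apply(model$sv, 1, as.numeric, simplify = FALSE)),
              sv_alpha = model$sv_alpha, sv_y = model$sv_y,
              n_features = model$n_features)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load an SVM model from JSON
#'
#' @param path JSON path written by [write_svm_model()].
#' @return An `svm_model` usable with [svm_predict()].
#' @export
read_svm_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  sv <- if (is.matrix(obj$sv)) obj$sv
    else if (length(obj$sv)) do.call(rbind, lapply(obj$sv, as.numeric))
    else matrix(0, 0, obj$n_features)
  structure(list(alpha = obj$sv_alpha, b = obj$b, sv = sv,
                 sv_alpha = obj$sv_alpha, sv_y = obj$sv_y,
                 sv_index = seq_along(obj$sv_alpha), weights = NULL,
                 kernel = kernel_spec(obj$kernel$kind, obj$kernel$gamma),
                 C = obj$C, n_features = obj$n_features,
                 n_samples = length(obj$sv_alpha)),
            class = "svm_model")
}
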
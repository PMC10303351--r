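# Plain-text and PNG persistence: masks and label maps as 8-bit PNG
# (0/128/255 coding), color-checker tables as CSV, and the calibration /
# score models as JSON.

#' Write an RGB image to PNG
#'
#' @param img H x W x 3 array in \[0, 1\].
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_image_png <- function(img, path) {
  png::writePNG(clamp01(as_rgb_array(img)), path)
  invisible(path)
}

#' Read an RGB image from PNG
#'
#' @param path PNG file; grayscale and alpha channels are expanded or
#'   dropped so the result is always H x W x 3.
#' @return H x W x 3 array in \[0, 1\].
#' @export
read_image_png <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 2) x <- array(rep(x, 3), c(dim(x), 3))
  if (dim(x)[3] == 4) x <- x[, , 1:3]
  if (dim(x)[3] == 2) x <- array(rep(x[, , 1], 3), c(dim(x)[1:2], 3))
  x
}

#' Write a response map (or any scalar raster) to float32 TIFF
#'
#' Values must lie in \[0, 1\] (TIFF float storage is undefined outside
#' that range), so rescale response maps — e.g. divide by their maximum —
#' before export; within the range, values round-trip to float precision.
#'
#' @param x Numeric matrix in \[0, 1\] (e.g. a rescaled Gabor
#'   max-response map).
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_raster_tiff <- function(x, path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("the 'tiff' package is required for TIFF export")
  }
  if (any(x < 0 | x > 1)) stop("raster values must lie in [0, 1]")
  tiff::writeTIFF(x, path, bits.per.sample = 32, reduce = FALSE)
  invisible(path)
}

#' Read a float32 TIFF raster
#'
#' @param path File written by [write_raster_tiff()].
#' @return Numeric matrix.
#' @export
read_raster_tiff <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("the 'tiff' package is required for TIFF import")
  }
  tiff::readTIFF(path)
}

#' Write a binary mask to PNG (0/255)
#'
#' @param mask Logical matrix.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask), nrow(mask)), path)
  invisible(path)
}

#' Read a binary mask from PNG
#'
#' @param path PNG file written by [write_mask_png()].
#' @return Logical matrix.
#' @export
read_mask_png <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3) x <- x[, , 1]
  x > 0.5
}

#' Write an artery/vein label map to PNG (0/128/255)
#'
#' Background maps to 0, artery to 128, vein to 255.
#'
#' @param labels Integer label map.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_labels_png <- function(labels, path) {
  x <- matrix(0, nrow(labels), ncol(labels))
  x[labels == AV_ARTERY] <- 128 / 255
  x[labels == AV_VEIN] <- 1
  png::writePNG(x, path)
  invisible(path)
}

#' Read an artery/vein label map from PNG
#'
#' @param path PNG file written by [write_labels_png()].
#' @return Integer label map (0/1/2).
#' @export
read_labels_png <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3) x <- x[, , 1]
  out <- matrix(AV_BACKGROUND, nrow(x), ncol(x))
  out[abs(x - 128 / 255) < 0.2] <- AV_ARTERY
  out[x > 0.9] <- AV_VEIN
  out
}

#' Write a color checker to CSV
#'
#' Spectra go to `spectra_path` (first column `wavelength_nm`, one column
#' per patch), camera RGB to `rgb_path` (24 x 3 with a `patch_id` column).
#'
#' @param checker A [color_checker()].
#' @param spectra_path,rgb_path Output CSV files.
#' @return Invisibly, the two paths.
#' @export
write_checker_csv <- function(checker, spectra_path, rgb_path) {
  sp <- data.frame(wavelength_nm = checker$wavelength, t(checker$spectra),
                   check.names = FALSE)
  utils::write.csv(sp, spectra_path, row.names = FALSE)
  rgb <- data.frame(patch_id = checker$patch_id, checker$rgb)
  utils::write.csv(rgb, rgb_path, row.names = FALSE)
  invisible(c(spectra_path, rgb_path))
}

#' Read a color checker from CSV
#'
#' @param spectra_path,rgb_path Files written by [write_checker_csv()].
#' @return A `color_checker` (without a camera model).
#' @export
read_checker_csv <- function(spectra_path, rgb_path) {
  sp <- utils::read.csv(spectra_path, check.names = FALSE)
  rgb <- utils::read.csv(rgb_path)
  spectra <- t(as.matrix(sp[, -1, drop = FALSE]))
  rownames(spectra) <- colnames(sp)[-1]
  structure(list(wavelength = sp$wavelength_nm, spectra = spectra,
                 rgb = as.matrix(rgb[, c("R", "G", "B")]),
                 patch_id = rgb$patch_id),
            class = "color_checker")
}

#' Persist a calibration model (basis + transformation matrix) as JSON
#'
#' @param tm A [fit_transformation()] result.
#' @param path Output JSON file.
#' @return The path, invisibly.
#' @export
write_model_json <- function(tm, path) {
  obj <- list(
    expansion = tm$expansion,
    ridge = tm$ridge,
    M = tm$M,
    basis = list(wavelength = tm$basis$wavelength, mean = tm$basis$mean,
                 vectors = tm$basis$vectors, values = tm$basis$values,
                 k = tm$basis$k))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a calibration model from JSON
#'
#' @param path File written by [write_model_json()].
#' @return A `transformation_matrix`.
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  basis <- structure(list(wavelength = obj$basis$wavelength,
                          mean = obj$basis$mean,
                          vectors = as.matrix(obj$basis$vectors),
                          values = obj$basis$values, k = obj$basis$k),
                     class = "spectral_basis")
  structure(list(M = as.matrix(obj$M), expansion = obj$expansion,
                 basis = basis, ridge = obj$ridge,
                 residual_rmse = NULL),
            class = "transformation_matrix")
}

#' Persist an artery/vein score model as JSON
#'
#' @param model A [fit_score_model()] result.
#' @param path Output JSON file.
#' @return The path, invisibly.
#' @export
write_score_model_json <- function(model, path) {
  obj <- list(center = model$center, loadings = model$loadings,
              values = model$values, minmax = model$minmax,
              threshold = model$threshold, artery_high = model$artery_high,
              stage = model$stage, method = model$method,
              wavelength = model$wavelength, n_train = model$n_train)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read an artery/vein score model from JSON
#'
#' @param path File written by [write_score_model_json()].
#' @return An `av_score_model`.
#' @export
read_score_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  mm <- as.matrix(obj$minmax)
  colnames(mm) <- c("min", "max")
  structure(list(center = obj$center, loadings = as.matrix(obj$loadings),
                 values = obj$values, minmax = mm,
                 threshold = obj$threshold, artery_high = obj$artery_high,
                 stage = obj$stage, method = obj$method,
                 wavelength = obj$wavelength, n_train = obj$n_train),
            class = "av_score_model")
}

#' Export a spectral cube as CSV
#'
#' One row per pixel: `row`, `col`, then one column per wavelength.
#'
#' @param cube A [reconstruct_cube()] result.
#' @param path Output CSV file.
#' @return The path, invisibly.
#' @export
write_cube_csv <- function(cube, path) {
  df <- data.frame(cube$coords, cube$spectra)
  colnames(df) <- c("row", "col", paste0("nm", cube$wavelength))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
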
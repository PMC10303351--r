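# Hyperspectral reconstruction from camera RGB: a six-eigenvector PCA
# basis fitted to calibration spectra, a ridge-regularised regression from
# polynomially expanded RGB to basis coefficients, and per-pixel spectrum
# simulation over a vessel mask.

#' Fit a PCA spectral basis to calibration spectra
#'
#' Removes the mean spectrum and eigendecomposes the sample covariance of
#' the calibration set, keeping the leading `k` (default 6) orthonormal
#' eigenvector spectra. Eigenvector signs are fixed so the largest-
#' magnitude loading of each is positive. Errors if the calibration set
#' has fewer than `k + 1` spectra or numerical rank below `k`.
#'
#' @param spectra A [color_checker()] or an n x B matrix of reflectance
#'   spectra (rows are samples).
#' @param k Number of eigenvectors to keep.
#' @param wavelength Wavelength grid; taken from the checker when
#'   `spectra` is a `color_checker`.
#' @return A list of class `spectral_basis` with `wavelength`, `mean`
#'   (mean spectrum), `vectors` (B x k orthonormal matrix), `values`
#'   (descending eigenvalues) and `k`.
#' @export
fit_spectral_basis <- function(spectra, k = 6, wavelength = NULL) {
  if (inherits(spectra, "color_checker")) {
    wavelength <- spectra$wavelength
    spectra <- spectra$spectra
  }
  spectra <- as.matrix(spectra)
  n <- nrow(spectra)
  if (is.null(wavelength)) wavelength <- seq_len(ncol(spectra))
  if (n < k + 1) {
    stop(sprintf("need at least %d spectra to fit a %d-vector basis", k + 1, k))
  }
  ctr <- colMeans(spectra)
  X <- sweep(spectra, 2, ctr)
  sv <- svd(X, nu = 0, nv = min(n - 1, ncol(X)))
  values <- sv$d^2 / (n - 1)
  rank <- sum(sv$d > max(sv$d) * 1e-8)
  if (rank < k) {
    stop(sprintf("calibration spectra have rank %d < %d; basis would be degenerate",
                 rank, k))
  }
  vectors <- sv$v[, seq_len(k), drop = FALSE]
  # sign fix: largest-|loading| entry positive
  for (j in seq_len(k)) {
    i <- which.max(abs(vectors[, j]))
    if (vectors[i, j] < 0) vectors[, j] <- -vectors[, j]
  }
  structure(list(wavelength = wavelength, mean = ctr, vectors = vectors,
                 values = values[seq_len(k)], k = k),
            class = "spectral_basis")
}

#' @export
print.spectral_basis <- function(x, ...) {
  cat(sprintf("<spectral_basis> %d eigenvectors on %d wavelengths; explained %.1f%%\n",
              x$k, length(x$wavelength),
              100 * sum(x$values) / max(sum(x$values), .Machine$double.eps)))
  invisible(x)
}

#' The fixed polynomial RGB feature expansion
#'
#' @return Character vector naming the 11 monomial terms.
#' @export
rgb_expansion <- function() {
  c("1", "R", "G", "B", "R2", "G2", "B2", "RG", "GB", "RB", "RGB")
}

#' Expand RGB triples into polynomial features
#'
#' Evaluates the fixed 11-term monomial list
#' `1, R, G, B, R^2, G^2, B^2, RG, GB, RB, RGB`.
#'
#' @param rgb Length-3 vector or n x 3 matrix.
#' @return 1 x 11 or n x 11 matrix with the terms as column names.
#' @export
#' @examples
#' expand_rgb(c(0.5, 0, 0))
expand_rgb <- function(rgb) {
  if (!is.matrix(rgb)) rgb <- matrix(rgb, nrow = 1)
  stopifnot(ncol(rgb) == 3, all(is.finite(rgb)))
  r <- rgb[, 1]; g <- rgb[, 2]; b <- rgb[, 3]
  out <- cbind(1, r, g, b, r^2, g^2, b^2, r * g, g * b, r * b, r * g * b)
  colnames(out) <- rgb_expansion()
  out
}

#' Fit the RGB-to-spectrum transformation matrix
#'
#' Projects each calibration patch spectrum onto the basis to get its
#' coefficient vector, then solves a (ridge-regularised) least-squares
#' regression from the expanded patch RGB to those coefficients. The
#' resulting matrix maps an 11-term RGB feature vector to `k` basis
#' coefficients.
#'
#' @param checker A [color_checker()], or any list with `rgb` (n x 3) and
#'   `spectra` (n x B) on the basis grid.
#' @param basis A [fit_spectral_basis()] result.
#' @param ridge Ridge regularizer (>= 0; 0 requires a nonsingular design).
#' @return A list of class `transformation_matrix` with `M` (k x 11),
#'   `expansion`, `basis` and the per-patch training `residual_rmse`
#'   (reflectance units, before clipping).
#' @export
fit_transformation <- function(checker, basis, ridge = 1e-6) {
  if (ridge < 0) stop("ridge must be >= 0")
  rgb <- checker$rgb
  spectra <- as.matrix(checker$spectra)
  if (ncol(spectra) != length(basis$wavelength)) {
    stop("checker spectra are not on the basis wavelength grid")
  }
  X <- expand_rgb(rgb)                                  # n x 11
  Y <- sweep(spectra, 2, basis$mean) %*% basis$vectors  # n x k
  XtX <- crossprod(X) + diag(ridge, ncol(X))
  M <- tryCatch(t(solve(XtX, crossprod(X, Y))),
                error = function(e) {
                  stop("singular design matrix; increase ridge", call. = FALSE)
                })
  fitted <- sweep((X %*% t(M)) %*% t(basis$vectors), 2, basis$mean, "+")
  rmse <- sqrt(rowMeans((fitted - spectra)^2))
  structure(list(M = M, expansion = rgb_expansion(), basis = basis,
                 ridge = ridge, residual_rmse = rmse),
            class = "transformation_matrix")
}

#' @export
print.transformation_matrix <- function(x, ...) {
  cat(sprintf("<transformation_matrix> %d x %d, ridge %g, training RMSE %.2g\n",
              nrow(x$M), ncol(x$M), x$ridge, mean(x$residual_rmse)))
  invisible(x)
}

#' Simulate reflectance spectra from pixel RGB values
#'
#' Reconstructs `mean + vectors %*% (M %*% expand_rgb(rgb))` for each
#' pixel; reflectances are clipped to \[0, 1\] unless `clip = FALSE`.
#'
#' @param rgb Length-3 vector or n x 3 matrix of pixel values.
#' @param tm A [fit_transformation()] result.
#' @param clip Clip the output to physical reflectance range.
#' @return Length-B vector or n x B matrix of reflectances.
#' @export
simulate_pixel_spectrum <- function(rgb, tm, clip = TRUE) {
  single <- !is.matrix(rgb)
  Phi <- expand_rgb(rgb)
  S <- sweep((Phi %*% t(tm$M)) %*% t(tm$basis$vectors), 2, tm$basis$mean, "+")
  if (clip) S <- clamp01(S)
  if (single) drop(S) else S
}

#' Reconstruct a spectral cube over a vessel mask
#'
#' Simulates one reflectance spectrum per masked pixel.
#'
#' @param img H x W x 3 RGB array.
#' @param mask Logical matrix of the same H x W.
#' @param tm A [fit_transformation()] result.
#' @param clip Clip spectra to \[0, 1\].
#' @return A list of class `spectral_cube` with `coords` (tibble
#'   `row`, `col`), `spectra` (n x B matrix), `wavelength` and `dim`.
#' @export
reconstruct_cube <- function(img, mask, tm, clip = TRUE) {
  img <- as_rgb_array(img)
  stopifnot(identical(dim(img)[1:2], dim(mask)))
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("mask selects no pixels")
  rgb <- cbind(img[, , 1][idx], img[, , 2][idx], img[, , 3][idx])
  spectra <- simulate_pixel_spectrum(rgb, tm, clip = clip)
  structure(list(coords = tibble::tibble(row = idx[, 1], col = idx[, 2]),
                 spectra = spectra, wavelength = tm$basis$wavelength,
                 dim = dim(mask)),
            class = "spectral_cube")
}

#' @export
print.spectral_cube <- function(x, ...) {
  cat(sprintf("<spectral_cube> %d pixels x %d wavelengths\n",
              nrow(x$spectra), ncol(x$spectra)))
  invisible(x)
}

# Label codes of a cube's pixels from a label map.
cube_labels <- function(cube, labels) {
  stopifnot(identical(dim(labels), cube$dim))
  labels[cbind(cube$coords$row, cube$coords$col)]
}

#' Mean reflectance spectrum of a labelled pixel class
#'
#' @param cube A [reconstruct_cube()] result.
#' @param labels Integer label map (0 background, 1 artery, 2 vein) of the
#'   cube's image dimensions.
#' @param class `"artery"` or `"vein"`.
#' @return Tibble with columns `wavelength`, `reflectance`, `class`, `n`.
#' @export
mean_class_spectrum <- function(cube, labels, class = "artery") {
  code <- av_code(class)
  lab <- cube_labels(cube, labels)
  sel <- lab == code
  if (!any(sel)) stop("class '", class, "' absent from the labelled pixels")
  tibble::tibble(wavelength = cube$wavelength,
                 reflectance = colMeans(cube$spectra[sel, , drop = FALSE]),
                 class = class, n = sum(sel))
}
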
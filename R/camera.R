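# Forward camera model: spectral sensitivities, illuminant, and the
# rendering of reflectance spectra to RGB. Used to build calibration
# fixtures (color checker) and to colour the synthetic phantoms.

#' Three-channel spectral camera model
#'
#' A simple trichromatic model: Gaussian channel sensitivities (peaks near
#' 600, 540 and 460 nm for R, G, B) under a flat illuminant, with a scalar
#' gain per channel. The model only needs to make RGB an informative
#' summary of a visible-band reflectance spectrum; it is not a
#' characterisation of any physical sensor.
#'
#' @param peaks Sensitivity peak wavelengths (nm) for R, G, B.
#' @param sds Gaussian widths (nm) per channel.
#' @param gain Per-channel scalar gain; rendering a perfect white with
#'   gain 1 yields RGB (1, 1, 1).
#' @param illuminant Spectral power per wavelength (recycled if scalar).
#' @param wavelength Wavelength grid in nm.
#' @return A list of class `camera_model` with elements `wavelength`,
#'   `sensitivities` (3 x B matrix, rows R, G, B), `illuminant`, `gain`.
#' @export
camera_model <- function(peaks = c(600, 540, 460), sds = c(40, 40, 40),
                         gain = c(1, 1, 1), illuminant = 1,
                         wavelength = wavelength_grid()) {
  stopifnot(length(peaks) == 3, length(sds) == 3)
  gain <- rep_len(gain, 3)
  illuminant <- rep_len(illuminant, length(wavelength))
  if (any(illuminant < 0)) stop("illuminant must be nonnegative")
  sens <- t(vapply(1:3, function(i) gauss_bump(wavelength, peaks[i], sds[i]),
                   numeric(length(wavelength))))
  rownames(sens) <- c("R", "G", "B")
  if (any(sens < 0) || any(rowSums(sens) <= 0)) {
    stop("channel sensitivities must be nonnegative with positive integral")
  }
  structure(list(wavelength = wavelength, sensitivities = sens,
                 illuminant = illuminant, gain = gain),
            class = "camera_model")
}

#' Render reflectance spectra to camera RGB
#'
#' Each channel is the illuminant-weighted integral of reflectance times
#' channel sensitivity, normalised by the integral of illuminant times
#' sensitivity, times the channel gain; values are clamped to \[0, 1\].
#' A flat 100% reflector therefore renders to (1, 1, 1) at unit gain and
#' a black sample to (0, 0, 0).
#'
#' @param reflectance A reflectance vector on the camera's grid, or an
#'   n x B matrix of spectra (rows are samples).
#' @param cam A [camera_model()].
#' @return A length-3 named vector (R, G, B), or an n x 3 matrix when
#'   `reflectance` is a matrix.
#' @export
camera_response <- function(reflectance, cam) {
  if (is.matrix(reflectance)) {
    if (ncol(reflectance) != length(cam$wavelength)) {
      stop("spectrum grid does not match the camera model grid")
    }
    W <- t(cam$sensitivities * rep(cam$illuminant, each = 3)) # B x 3
    norm <- colSums(W)
    rgb <- sweep(reflectance %*% W, 2, norm, "/")
    rgb <- sweep(rgb, 2, cam$gain, "*")
    colnames(rgb) <- c("R", "G", "B")
    return(clamp01(rgb))
  }
  if (length(reflectance) != length(cam$wavelength)) {
    stop("spectrum grid does not match the camera model grid")
  }
  drop(camera_response(matrix(reflectance, nrow = 1), cam))
}

#' Synthetic 24-patch color checker
#'
#' Generates a calibration target in the spirit of the standard 24-patch
#' color checker: 20 smooth random reflectance spectra (seeded, spanning
#' low to high reflectance) plus 4 neutral (spectrally flat) patches, each
#' rendered to camera RGB through the forward model. The random spectra
#' are logistic-squashed sums of broad Gaussian bumps, which keeps them
#' smooth, inside (0, 1), and jointly of rank well above the 6 needed for
#' the spectral basis.
#'
#' @param cam A [camera_model()].
#' @param seed Integer seed; the set is a pure function of it.
#' @param n_random Number of random patches (the remaining 4 are neutral).
#' @return A list of class `color_checker` with `wavelength`, `spectra`
#'   (24 x B matrix), `rgb` (24 x 3), `patch_id`.
#' @export
color_checker <- function(cam = camera_model(), seed = 1, n_random = 20) {
  wl <- cam$wavelength
  n_bumps <- 8
  centers <- seq(min(wl), max(wl), length.out = n_bumps)
  basis <- vapply(centers, function(cc) gauss_bump(wl, cc, 70),
                  numeric(length(wl)))
  spectra <- with_seed(seed, {
    w <- matrix(stats::rnorm(n_random * n_bumps, sd = 1.2), n_random)
    a0 <- stats::rnorm(n_random, sd = 1)
    z <- w %*% t(basis) + a0
    0.03 + 0.94 * stats::plogis(z)
  })
  neutrals <- outer(c(0.10, 0.30, 0.60, 0.85), rep(1, length(wl)))
  spectra <- rbind(spectra, neutrals)
  rownames(spectra) <- sprintf("patch_%02d", seq_len(nrow(spectra)))
  structure(list(wavelength = wl, spectra = spectra,
                 rgb = camera_response(spectra, cam),
                 patch_id = rownames(spectra)),
            class = "color_checker")
}

#' @export
print.color_checker <- function(x, ...) {
  cat(sprintf("<color_checker> %d patches, %d wavelengths (%g-%g nm)\n",
              nrow(x$spectra), length(x$wavelength),
              min(x$wavelength), max(x$wavelength)))
  invisible(x)
}

#' Tidy a color checker into a long tibble
#'
#' @param x A `color_checker`.
#' @param ... Unused.
#' @return Tibble with columns `patch_id`, `wavelength`, `reflectance`.
#' @export
tidy.color_checker <- function(x, ...) {
  tibble::tibble(
    patch_id = rep(x$patch_id, each = length(x$wavelength)),
    wavelength = rep(x$wavelength, times = nrow(x$spectra)),
    reflectance = as.vector(t(x$spectra))
  )
}
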
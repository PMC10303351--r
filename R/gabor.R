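# Oriented Gabor filter bank for vessel enhancement. The kernel is a
# Gaussian envelope modulated by a sinusoidal plane wave evaluated on
# rotated coordinates; an image is correlated with the real and imaginary
# kernels at every orientation and only the maximum magnitude response is
# retained per pixel.

#' Gabor filter-bank parameters
#'
#' @param f0 Spatial frequency of the modulating wave, cycles/pixel.
#' @param sigma_x,sigma_y Gaussian envelope standard deviations (px) along
#'   the rotated x' and y' axes.
#' @param theta_step Orientation step in radians; the bank covers
#'   \[-pi/2, pi/2\] inclusive, so the default pi/180 yields 181 angles.
#' @param halfwidth Kernel half-width in px; defaults to at least three
#'   envelope standard deviations.
#' @return A list of class `gabor_params`.
#' @export
gabor_params <- function(f0 = 1 / 8, sigma_x = 1.5, sigma_y = 3,
                         theta_step = pi / 180, halfwidth = NULL) {
  if (f0 <= 0) stop("f0 must be positive")
  if (sigma_x <= 0 || sigma_y <= 0) stop("sigmas must be positive")
  if (theta_step <= 0) stop("theta_step must be positive")
  if (is.null(halfwidth)) halfwidth <- ceiling(3 * max(sigma_x, sigma_y))
  halfwidth <- as.integer(halfwidth)
  if (halfwidth < 1) stop("halfwidth must be >= 1")
  structure(list(f0 = f0, sigma_x = sigma_x, sigma_y = sigma_y,
                 theta_step = theta_step, halfwidth = halfwidth),
            class = "gabor_params")
}

#' Orientation grid of a Gabor bank
#'
#' @param p A [gabor_params()].
#' @return Angles in radians from -pi/2 to pi/2 inclusive.
#' @export
gabor_thetas <- function(p) {
  seq(-pi / 2, pi / 2, by = p$theta_step)
}

#' Real and imaginary Gabor kernels at one orientation
#'
#' On the square grid of half-width `p$halfwidth` centred at the origin
#' (kernel x increasing with column, y with row), coordinates are rotated
#' by theta (`x' = x cos t + y sin t`, `y' = -x sin t + y cos t`) and the
#' kernels are the Gaussian envelope `exp(-(x'^2/sx^2 + y'^2/sy^2)/2) /
#' (2 pi sx sy)` times `cos(2 pi f0 x')` (real) or `sin(2 pi f0 x')`
#' (imaginary). The real kernel is even and the imaginary kernel odd under
#' point reflection.
#'
#' @param p A [gabor_params()].
#' @param theta Orientation in radians.
#' @return List with square matrices `real` and `imag` and the `theta`.
#' @export
gabor_kernel <- function(p, theta) {
  h <- p$halfwidth
  x <- matrix(rep(seq(-h, h), each = 2 * h + 1), 2 * h + 1) # col offsets
  y <- matrix(rep(seq(-h, h), times = 2 * h + 1), 2 * h + 1) # row offsets
  xp <- x * cos(theta) + y * sin(theta)
  yp <- -x * sin(theta) + y * cos(theta)
  env <- exp(-0.5 * (xp^2 / p$sigma_x^2 + yp^2 / p$sigma_y^2)) /
    (2 * pi * p$sigma_x * p$sigma_y)
  list(real = env * cos(2 * pi * p$f0 * xp),
       imag = env * sin(2 * pi * p$f0 * xp),
       theta = theta)
}

# Reflection-pad a matrix by h pixels on every side.
reflect_pad <- function(img, h) {
  H <- nrow(img); W <- ncol(img)
  if (h >= H || h >= W) stop("kernel larger than the image allows")
  img[c(h:1, 1:H, H:(H - h + 1)), c(h:1, 1:W, W:(W - h + 1))]
}

# FFT of a reflection-padded image, reused across the whole bank.
pad_fft <- function(gray, h) {
  P <- reflect_pad(gray, h)
  list(F = stats::fft(P), Hp = nrow(P), Wp = ncol(P), h = h,
       H = nrow(gray), W = ncol(gray))
}

# Correlation of the padded image with a (possibly complex) kernel via
# circular FFT correlation; exact on the interior because the reflection
# pad is at least as wide as the kernel half-width.
corr_with_kernel <- function(pf, kernel) {
  h <- pf$h
  K <- matrix(0 + 0i, pf$Hp, pf$Wp)
  wrap <- function(d, n) ((d %% n) + n) %% n + 1L
  idx_r <- wrap(seq(-h, h), pf$Hp)
  idx_c <- wrap(seq(-h, h), pf$Wp)
  K[idx_r, idx_c] <- kernel
  out <- stats::fft(pf$F * Conj(stats::fft(K)), inverse = TRUE) /
    (pf$Hp * pf$Wp)
  out[h + seq_len(pf$H), h + seq_len(pf$W)]
}

#' Oriented Gabor response of a grayscale image
#'
#' Correlates (no kernel flip) the image with the real and imaginary
#' Gabor kernels at one orientation. Boundaries are handled by reflection
#' padding; output shape equals input shape.
#'
#' @param gray Numeric matrix (grayscale image).
#' @param p A [gabor_params()].
#' @param theta Orientation in radians.
#' @return List of class `oriented_response` with matrices `real`,
#'   `imag` and the `theta`.
#' @export
oriented_response <- function(gray, p, theta) {
  stopifnot_raster(gray)
  k <- gabor_kernel(p, theta)
  pf <- pad_fft(gray, p$halfwidth)
  # corr(I, kr + i*ki) appears conjugated through the FFT: real part is
  # the correlation with kr, the negated imaginary part with ki.
  cplx <- corr_with_kernel(pf, k$real + 1i * k$imag)
  structure(list(real = Re(cplx), imag = -Im(cplx), theta = theta),
            class = "oriented_response")
}

#' Magnitude of an oriented Gabor response
#'
#' Pointwise root-sum-of-squares of the real and imaginary component
#' responses (the complex magnitude).
#'
#' @param resp An `oriented_response`, or a list with `real`/`imag`.
#' @return Nonnegative matrix of the same shape.
#' @export
magnitude_response <- function(resp) {
  stopifnot(identical(dim(resp$real), dim(resp$imag)))
  sqrt(resp$real^2 + resp$imag^2)
}

#' Maximum Gabor response over the orientation bank
#'
#' Runs the full bank (default 181 orientations over \[-pi/2, pi/2\]) and
#' keeps, per pixel, only the maximum magnitude response together with the
#' orientation attaining it.
#'
#' @param gray Numeric matrix (typically the green channel).
#' @param p A [gabor_params()].
#' @param thetas Optional explicit orientation grid (radians); defaults to
#'   [gabor_thetas()].
#' @return List of class `response_map` with `response` (max magnitude),
#'   `argmax_theta` (radians) and `thetas`.
#' @export
max_response_map <- function(gray, p = gabor_params(), thetas = NULL) {
  stopifnot_raster(gray)
  if (is.null(thetas)) thetas <- gabor_thetas(p)
  if (length(thetas) == 0) stop("orientation grid is empty")
  pf <- pad_fft(gray, p$halfwidth)
  best <- matrix(-Inf, nrow(gray), ncol(gray))
  arg <- matrix(thetas[1], nrow(gray), ncol(gray))
  for (th in thetas) {
    k <- gabor_kernel(p, th)
    cplx <- corr_with_kernel(pf, k$real + 1i * k$imag)
    mag <- Mod(cplx)
    upd <- mag > best
    best[upd] <- mag[upd]
    arg[upd] <- th
  }
  structure(list(response = best, argmax_theta = arg, thetas = thetas),
            class = "response_map")
}
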
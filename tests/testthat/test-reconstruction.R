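test_that("in-span scenes reconstruct to machine precision", {
  fx <- inspan_fixture(seed = 42)
  tm <- fit_transformation(fx$checker, fx$basis, ridge = 0)
  recon <- simulate_pixel_spectrum(fx$scene$rgb, tm)
  rmse <- sqrt(rowMeans((recon - fx$scene$spectra)^2))
  expect_lt(max(rmse), 1e-6)
  # clipping never fires on the noiseless in-span fixture
  unclipped <- simulate_pixel_spectrum(fx$scene$rgb, tm, clip = FALSE)
  expect_identical(recon, unclipped)
})

test_that("a zero transformation maps every pixel to the mean spectrum", {
  cal <- default_calibration()
  tm0 <- cal$tm
  tm0$M[] <- 0
  sp <- simulate_pixel_spectrum(c(0.3, 0.6, 0.2), tm0)
  expect_equal(sp, pmin(pmax(cal$basis$mean, 0), 1), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("cube reconstruction enumerates exactly the masked pixels", {
  cal <- default_calibration()
  img <- array(stats::runif(64 * 64 * 3), c(64, 64, 3))
  mask <- matrix(stats::runif(64 * 64) < 0.2, 64, 64)
  cube <- reconstruct_cube(img, mask, cal$tm)
  expect_equal(nrow(cube$spectra), sum(mask))
  expect_equal(nrow(cube$coords), sum(mask))
  # single-pixel mask reduces to simulate_pixel_spectrum
  m1 <- matrix(FALSE, 64, 64); m1[10, 20] <- TRUE
  cube1 <- reconstruct_cube(img, m1, cal$tm)
  expect_equal(drop(cube1$spectra),
               simulate_pixel_spectrum(img[10, 20, ], cal$tm),
               ignore_attr = TRUE)
  expect_error(reconstruct_cube(img, matrix(FALSE, 64, 64), cal$tm),
               "no pixels")
})

test_that("reconstruction preserves the artery-vein spectral contrast", {
  # absolute spectra carry a common-mode calibration bias (vessel colours
  # are extrapolations outside the checker's RGB cloud), but the
  # artery-vein difference, which drives classification, must survive
  cal <- default_calibration()
  sc <- phantom_fundus("normal", size = 192, seed = 4, noise_sd = 0,
                       cam = cal$cam)
  cube <- reconstruct_cube(sc$image, sc$vessel_mask, cal$tm)
  ma <- mean_class_spectrum(cube, sc$av_labels, "artery")
  mv <- mean_class_spectrum(cube, sc$av_labels, "vein")
  true_diff <- sc$spectra$artery - sc$spectra$vein
  recon_diff <- ma$reflectance - mv$reflectance
  expect_gt(stats::cor(recon_diff, true_diff), 0.5)
  # red-band ordering carries through reconstruction
  red <- cube$wavelength >= 620
  expect_gt(mean(ma$reflectance[red]), mean(mv$reflectance[red]))
  # the artery reconstruction is nearer the artery truth than the vein
  # reconstruction is
  rmse <- function(a, b) sqrt(mean((a - b)^2))
  expect_lt(rmse(ma$reflectance, sc$spectra$artery),
            rmse(mv$reflectance, sc$spectra$artery))
  expect_error(mean_class_spectrum(cube, sc$av_labels * 0L, "artery"),
               "absent")
})

test_that("reconstruction error grows monotonically with RGB noise", {
  # measured in the in-span world, where the reconstruction error is
  # noise-driven rather than dominated by calibration bias
  fx <- inspan_fixture(seed = 42)
  tm <- fit_transformation(fx$checker, fx$basis, ridge = 0)
  set.seed(22)
  mean_rmse <- vapply(c(0, 0.005, 0.01, 0.02), function(sd) {
    noisy <- pmin(pmax(fx$scene$rgb +
                         matrix(stats::rnorm(length(fx$scene$rgb), sd = sd),
                                nrow(fx$scene$rgb)), 0), 1)
    recon <- simulate_pixel_spectrum(noisy, tm)
    mean(sqrt(rowMeans((recon - fx$scene$spectra)^2)))
  }, numeric(1))
  expect_true(all(diff(mean_rmse) > 0))
})
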
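test_that("kernel centre values follow the closed form", {
  p <- gabor_params(f0 = 0.1, sigma_x = 2, sigma_y = 3, halfwidth = 6)
  for (th in c(-pi / 2, -0.3, 0, 0.7, pi / 2)) {
    k <- gabor_kernel(p, th)
    centre <- p$halfwidth + 1
    expect_equal(k$real[centre, centre], 1 / (2 * pi * 2 * 3))
    expect_equal(k$imag[centre, centre], 0)
  }
})

test_that("real kernels are even and imaginary kernels odd, all 181 angles", {
  p <- gabor_params()
  flip <- function(m) m[rev(seq_len(nrow(m))), rev(seq_len(ncol(m)))]
  for (th in gabor_thetas(p)) {
    k <- gabor_kernel(p, th)
    expect_equal(flip(k$real), k$real, tolerance = 1e-12)
    expect_equal(flip(k$imag), -k$imag, tolerance = 1e-12)
  }
})

test_that("theta = 0 and theta = pi/2 kernels are 90-degree rotations", {
  p <- gabor_params(sigma_x = 1.5, sigma_y = 2.5, halfwidth = 5)
  k0 <- gabor_kernel(p, 0)
  k90 <- gabor_kernel(p, pi / 2)
  rot90 <- function(m) t(m)[, rev(seq_len(nrow(m)))]
  # at theta = 0, x' = x (columns); at pi/2, x' = y (rows)
  expect_equal(k90$real, rot90(k0$real), tolerance = 1e-12)
  expect_equal(abs(k90$imag), abs(rot90(k0$imag)), tolerance = 1e-12)
})

test_that("oriented responses match the naive four-loop correlation", {
  set.seed(11)
  p <- gabor_params(halfwidth = 5)
  for (rep in 1:2) {
    img <- matrix(runif(32 * 32), 32)
    for (th in c(-pi / 2, -0.6, 0, 1.1)) {
      k <- gabor_kernel(p, th)
      resp <- oriented_response(img, p, th)
      expect_lt(max(abs(resp$real - naive_correlation(img, k$real))), 1e-8)
      expect_lt(max(abs(resp$imag - naive_correlation(img, k$imag))), 1e-8)
    }
  }
})

test_that("constant images give flat real response and null imaginary", {
  p <- gabor_params(halfwidth = 6)
  img <- matrix(0.7, 20, 20)
  k <- gabor_kernel(p, 0.4)
  resp <- oriented_response(img, p, 0.4)
  expect_equal(resp$real, matrix(0.7 * sum(k$real), 20, 20),
               tolerance = 1e-10)
  expect_lt(max(abs(resp$imag)), 1e-10)
})

test_that("an impulse reproduces the point-reflected kernel", {
  p <- gabor_params(halfwidth = 4)
  img <- matrix(0, 21, 21)
  img[11, 11] <- 1
  k <- gabor_kernel(p, 0.3)
  resp <- oriented_response(img, p, 0.3)
  # correlation: response(x) = kernel(p - x) around the impulse
  sub <- resp$imag[11 + seq(-4, 4), 11 + seq(-4, 4)]
  flip <- function(m) m[rev(seq_len(nrow(m))), rev(seq_len(ncol(m)))]
  expect_equal(sub, flip(k$imag), tolerance = 1e-10)
  expect_equal(resp$real[11 + seq(-4, 4), 11 + seq(-4, 4)], flip(k$real),
               tolerance = 1e-10)
})

test_that("magnitude response is the complex modulus", {
  resp <- list(real = matrix(3, 2, 2), imag = matrix(4, 2, 2))
  expect_equal(magnitude_response(resp), matrix(5, 2, 2))
  set.seed(2)
  r <- matrix(rnorm(25), 5); i <- matrix(rnorm(25), 5)
  expect_equal(magnitude_response(list(real = r, imag = i)),
               sqrt(r^2 + i^2))
  expect_equal(magnitude_response(list(real = r, imag = r * 0)), abs(r))
})

test_that("the max response dominates every per-angle magnitude map", {
  set.seed(3)
  img <- matrix(runif(40 * 40), 40)
  p <- gabor_params(halfwidth = 5)
  sub <- seq(-pi / 2, pi / 2, length.out = 10)
  rm_full <- max_response_map(img, p)
  rm_sub <- max_response_map(img, p, thetas = sub)
  for (th in sub) {
    mag <- magnitude_response(oriented_response(img, p, th))
    expect_true(all(rm_full$response >= mag - 1e-10))
  }
  expect_true(all(rm_full$response >= rm_sub$response - 1e-10))
})

test_that("a single-angle bank reduces to that angle's magnitude", {
  set.seed(4)
  img <- matrix(runif(30 * 30), 30)
  p <- gabor_params(halfwidth = 5)
  rm1 <- max_response_map(img, p, thetas = 0.5)
  expect_equal(rm1$response,
               magnitude_response(oriented_response(img, p, 0.5)))
})

test_that("argmax orientation tracks a straight synthetic vessel", {
  p <- gabor_params()
  for (ang_deg in c(0, 30, 60, 90)) {
    ang <- ang_deg * pi / 180
    n <- 64
    img <- matrix(0, n, n)
    # bright line through the centre at angle `ang` from the x (column) axis
    for (t in seq(-n / 2, n / 2, by = 0.25)) {
      r <- round(n / 2 - t * sin(ang)); cc <- round(n / 2 + t * cos(ang))
      if (r >= 1 && r <= n && cc >= 1 && cc <= n) img[r, cc] <- 1
    }
    rm <- max_response_map(img, p)
    centre <- img > 0 &
      row(img) > 16 & row(img) < n - 16 & col(img) > 16 & col(img) < n - 16
    got <- rm$argmax_theta[centre]
    # the wave axis x' is perpendicular to the ridge, so a vessel at angle
    # `ang` above the column axis peaks at theta = pi/2 - ang (modulo pi)
    expected <- pi / 2 - ang
    delta <- atan2(sin(2 * (got - expected)), cos(2 * (got - expected))) / 2
    expect_lt(abs(stats::median(delta)) * 180 / pi, 3)
  }
})

test_that("invalid Gabor parameters are rejected", {
  expect_error(gabor_params(f0 = 0), "f0")
  expect_error(gabor_params(sigma_x = -1), "sigma")
  expect_error(oriented_response(matrix(1, 4, 4), gabor_params(), 0),
               "kernel larger")
  expect_equal(length(gabor_thetas(gabor_params())), 181)
})
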
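# small helper: wrap a spectra matrix + label vector as a 1-column cube
as_cube <- function(spectra, wavelength = seq_len(ncol(spectra))) {
  structure(list(coords = tibble::tibble(row = seq_len(nrow(spectra)),
                                         col = 1L),
                 spectra = spectra, wavelength = wavelength,
                 dim = c(nrow(spectra), 1L)),
            class = "spectral_cube")
}

label_matrix <- function(lab) matrix(lab, length(lab), 1)

two_cluster_fixture <- function(n = 60, gap = 1, noise = 0.05, seed = 14) {
  set.seed(seed)
  B <- 20
  dir <- rep(1 / sqrt(B), B)
  lab <- rep(c(1L, 2L), each = n / 2)
  shift <- ifelse(lab == 1L, gap / 2, -gap / 2)
  spectra <- outer(shift, dir) + matrix(rnorm(n * B, sd = noise), n, B) + 0.5
  list(cube = as_cube(spectra), labels = label_matrix(lab), lab = lab)
}

test_that("two separated clusters give a bimodal PC1 and a threshold between", {
  fx <- two_cluster_fixture()
  model <- fit_score_model(fx$cube, fx$labels)
  sc <- score_pixels(fx$cube, model)
  mu_a <- mean(sc$s1[fx$lab == 1L]); mu_v <- mean(sc$s1[fx$lab == 2L])
  expect_gt(abs(mu_a - mu_v), 0.5) # well-separated normalized means
  expect_true(model$threshold > min(mu_a, mu_v) &&
                model$threshold < max(mu_a, mu_v))
  cls <- classify_pixels(sc, model)
  expect_equal(cls$label, ifelse(fx$lab == 1L, "artery", "vein"))
})

test_that("duplicating every pixel leaves the model unchanged", {
  fx <- two_cluster_fixture()
  m1 <- fit_score_model(fx$cube, fx$labels)
  dup <- as_cube(rbind(fx$cube$spectra, fx$cube$spectra))
  m2 <- fit_score_model(dup, label_matrix(c(fx$lab, fx$lab)))
  expect_equal(m1$loadings, m2$loadings, tolerance = 1e-8)
  expect_equal(m1$threshold, m2$threshold, tolerance = 1e-8)
  expect_equal(m1$minmax, m2$minmax, tolerance = 1e-8)
})

test_that("class orientation is learned, not hard-coded", {
  fx <- two_cluster_fixture()
  swapped <- label_matrix(ifelse(fx$lab == 1L, 2L, 1L))
  m <- fit_score_model(fx$cube, swapped)
  cls <- classify_pixels(score_pixels(fx$cube, m), m)
  expect_equal(cls$label, ifelse(fx$lab == 1L, "vein", "artery"))
})

test_that("degenerate inputs are rejected", {
  fx <- two_cluster_fixture()
  expect_error(fit_score_model(fx$cube, label_matrix(rep(1L, 60))),
               "both")
  two <- as_cube(fx$cube$spectra[1:2, ])
  expect_error(fit_score_model(two, label_matrix(c(1L, 2L))), "at least 3")
  flat <- as_cube(matrix(0.5, 10, 20))
  expect_error(fit_score_model(flat, label_matrix(rep(c(1L, 2L), 5))),
               "zero")
})

test_that("min-max normalization is the affine map with clamping", {
  mm <- rbind(c(min = 2, max = 6), c(min = -1, max = 1))
  s <- rbind(c(2, -1), c(6, 1), c(4, 0), c(0, 5))
  out <- minmax_normalize(s, mm)
  expect_equal(out[1, ], c(0, 0))
  expect_equal(out[2, ], c(1, 1))
  expect_equal(out[3, ], c(0.5, 0.5))
  expect_equal(out[4, ], c(0, 1)) # clamped extremes
  bad <- rbind(c(min = 2, max = 2), c(min = 0, max = 1))
  expect_error(minmax_normalize(s, bad), "strictly below")
})

test_that("labels are invariant to increasing affine maps of raw scores", {
  set.seed(15)
  raw <- stats::rnorm(100)
  mm <- rbind(cbind(min = min(raw), max = max(raw)),
              c(min = 0, max = 1))
  s <- cbind(raw, stats::runif(100))
  base <- minmax_normalize(s, mm)
  for (ab in list(c(2, 3), c(0.1, -5), c(7, 0))) {
    raw2 <- ab[1] * raw + ab[2]
    mm2 <- rbind(cbind(min = min(raw2), max = max(raw2)),
                 c(min = 0, max = 1))
    got <- minmax_normalize(cbind(raw2, s[, 2]), mm2)
    expect_equal(got[, 1], base[, 1], tolerance = 1e-10)
  }
})

test_that("the f1-scan threshold method also separates the clusters", {
  fx <- two_cluster_fixture()
  m <- fit_score_model(fx$cube, fx$labels, method = "f1_scan")
  cls <- classify_pixels(score_pixels(fx$cube, m), m)
  expect_equal(mean(cls$label == ifelse(fx$lab == 1L, "artery", "vein")), 1)
})

test_that("full-pipeline classification on a noiseless phantom is >= 90%", {
  cal <- default_calibration()
  sc <- phantom_fundus("normal", size = 256, seed = 9, noise_sd = 0,
                       cam = cal$cam)
  cube <- reconstruct_cube(sc$image, sc$vessel_mask, cal$tm)
  model <- fit_score_model(cube, sc$av_labels, stage = "normal")
  pred <- classify_cube(cube, model)
  m <- av_metrics(pred, sc$av_labels)
  expect_true(all(m$sensitivity >= 90))
  expect_true(all(m$precision >= 90))
})

test_that("the overlay paints arteries red and veins blue only", {
  img <- array(0.5, c(8, 8, 3))
  lab <- matrix(0L, 8, 8)
  expect_identical(render_overlay(img, lab), img)
  lab[2, 3] <- 1L; lab[5, 6] <- 2L
  out <- render_overlay(img, lab)
  expect_equal(out[2, 3, ], c(1, 0, 0))
  expect_equal(out[5, 6, ], c(0, 0, 1))
  # exactly two pixels changed
  expect_equal(sum(apply(out != img, c(1, 2), any)), 2)
  expect_equal(sum(out[, , 1] == 1 & out[, , 2] == 0 & out[, , 3] == 0),
               sum(lab == 1L))
  expect_error(render_overlay(img, matrix(0L, 4, 4)), "mismatch")
})

test_that("tidy and glance summarise a fitted score model", {
  fx <- two_cluster_fixture()
  m <- fit_score_model(fx$cube, fx$labels, stage = "normal")
  td <- tidy(m)
  expect_equal(nrow(td), 2 * 20)
  expect_named(td, c("wavelength", "component", "loading"))
  gl <- glance(m)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$stage, "normal")
  expect_gte(gl$var_pc1, gl$var_pc2)
})
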
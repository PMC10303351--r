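# Shared fixtures built in code at test time.

# An exactly linear calibration world: scene spectra lie in the span of a
# 6-eigenvector basis and the basis coefficients are an exact linear
# function of (R, G, B), so zero-ridge regression on the polynomial
# expansion must recover the mapping to machine precision.
inspan_fixture <- function(seed = 42, n_patches = 24, n_scene = 50) {
  cam <- camera_model()
  basis <- fit_spectral_basis(color_checker(cam, seed = seed), k = 6)
  set.seed(seed)
  # coefficients confined to a 3-dim subspace, linear in RGB
  Tmap <- matrix(rnorm(6 * 3, sd = 0.15), 6, 3)
  make_world <- function(n) {
    rgb <- matrix(runif(n * 3), n, 3)
    coeff <- rgb %*% t(Tmap)
    spectra <- sweep(coeff %*% t(basis$vectors), 2, basis$mean, "+")
    list(rgb = rgb, coeff = coeff, spectra = spectra)
  }
  calib <- make_world(n_patches)
  scene <- make_world(n_scene)
  checker <- structure(list(wavelength = basis$wavelength,
                            spectra = calib$spectra, rgb = calib$rgb,
                            patch_id = sprintf("patch_%02d",
                                               seq_len(n_patches))),
                       class = "color_checker")
  list(cam = cam, basis = basis, checker = checker,
       calib = calib, scene = scene, Tmap = Tmap)
}

# Default phantom for segmentation checks (noiseless, standard size).
default_phantom <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- phantom_fundus("normal", size = 256, seed = 1, noise_sd = 0)
    }
    cache
  }
})

# Calibration products shared by reconstruction tests.
default_calibration <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cam <- camera_model()
      checker <- color_checker(cam, seed = 1)
      basis <- fit_spectral_basis(checker, k = 6)
      cache <<- list(cam = cam, checker = checker, basis = basis,
                     tm = fit_transformation(checker, basis, ridge = 1e-6))
    }
    cache
  }
})

# The full four-stage, ten-replicate study used by the recovery and
# severity-trend checks; computed once and shared between them.
acceptance_av_experiment <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- run_config(n_images = 10, noise_sd = 0.01,
                        split_fraction = 0.30, seed = 7)
      cache <<- run_av_experiment(cfg, n_seeds = 10)
    }
    cache
  }
})
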
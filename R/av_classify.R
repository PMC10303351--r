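# Artery-vein classification: per-stage PCA of vessel-pixel spectra to
# two components, min-max normalization of the scores to [0,1], and a
# scalar decision threshold on the first-component axis.

#' Fit a per-stage artery/vein score model
#'
#' Runs a 2-component PCA (sign-fixed as in [fit_spectral_basis()]) on the
#' cube's pixel spectra, records min-max normalization bounds from the
#' training scores, learns which side of the first-component axis the
#' artery class occupies from the labelled training means, and places the
#' decision threshold on normalized component 1.
#'
#' Threshold methods: `"midpoint"` (default) uses the midpoint of the
#' class-conditional means of normalized component 1; `"f1_scan"` sweeps
#' thresholds in 0.01 steps and keeps the one maximizing the mean of the
#' artery and vein training F1 scores.
#'
#' @param cube A [reconstruct_cube()] result (training pixels).
#' @param labels Integer label map with both classes present on the cube's
#'   pixels.
#' @param stage Optional stage name stored with the model.
#' @param method Threshold selection method.
#' @return A list of class `av_score_model` with `center`, `loadings`
#'   (B x 2 orthonormal), `values`, `minmax` (2 x 2: rows components,
#'   columns min/max), `threshold`, `artery_high`, `stage`, `method`,
#'   `wavelength`, `n_train`.
#' @export
fit_score_model <- function(cube, labels, stage = NULL,
                            method = c("midpoint", "f1_scan")) {
  method <- match.arg(method)
  lab <- cube_labels(cube, labels)
  keep <- lab %in% c(AV_ARTERY, AV_VEIN)
  X <- cube$spectra[keep, , drop = FALSE]
  lab <- lab[keep]
  if (nrow(X) < 3) stop("need at least 3 labelled vessel pixels")
  if (length(unique(lab)) < 2) {
    stop("labels must contain both artery and vein pixels")
  }
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  # spectra live in a low-dimensional space; eigen of the small covariance
  cv <- crossprod(Xc) / (nrow(Xc) - 1)
  eg <- eigen(cv, symmetric = TRUE)
  if (eg$values[1] <= .Machine$double.eps) {
    stop("degenerate (zero-variance) spectra; cannot fit a score model")
  }
  loadings <- eg$vectors[, 1:2, drop = FALSE]
  for (j in 1:2) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) loadings[, j] <- -loadings[, j]
  }
  scores <- Xc %*% loadings
  mm <- cbind(min = apply(scores, 2, min), max = apply(scores, 2, max))
  if (mm[1, "min"] == mm[1, "max"]) {
    stop("zero component-1 score range; cannot min-max normalize")
  }
  if (mm[2, "min"] == mm[2, "max"]) {
    # exactly one-dimensional data: give component 2 a unit surrogate range
    mm[2, "max"] <- mm[2, "min"] + 1
  }
  s1 <- (scores[, 1] - mm[1, "min"]) / (mm[1, "max"] - mm[1, "min"])
  mu_a <- mean(s1[lab == AV_ARTERY])
  mu_v <- mean(s1[lab == AV_VEIN])
  artery_high <- mu_a >= mu_v
  threshold <- if (method == "midpoint") {
    (mu_a + mu_v) / 2
  } else {
    grid <- seq(0.01, 0.99, by = 0.01)
    score_of <- vapply(grid, function(th) {
      pred <- ifelse((s1 >= th) == artery_high, AV_ARTERY, AV_VEIN)
      mean(c(class_f1(pred, lab, AV_ARTERY), class_f1(pred, lab, AV_VEIN)))
    }, numeric(1))
    grid[which.max(score_of)]
  }
  structure(list(center = ctr, loadings = loadings,
                 values = eg$values[1:2], minmax = mm,
                 threshold = threshold, artery_high = artery_high,
                 stage = stage, method = method,
                 wavelength = cube$wavelength, n_train = nrow(X)),
            class = "av_score_model")
}

# training-time F1 helper tolerant of empty classes
class_f1 <- function(pred, truth, code) {
  tp <- sum(pred == code & truth == code)
  fp <- sum(pred == code & truth != code)
  fn <- sum(pred != code & truth == code)
  if (tp == 0) return(0)
  s <- tp / (tp + fn); p <- tp / (tp + fp)
  200 * s * p / (s + p)
}

#' Min-max normalize component scores
#'
#' Affine map `(s - min) / (max - min)` per component using stored
#' training bounds; out-of-range values (unseen test extremes) are
#' clamped to \[0, 1\].
#'
#' @param scores n x 2 matrix of raw component scores.
#' @param minmax 2 x 2 matrix (rows components, columns `min`, `max`).
#' @return n x 2 matrix in \[0, 1\].
#' @export
minmax_normalize <- function(scores, minmax) {
  if (any(minmax[, "min"] >= minmax[, "max"])) {
    stop("min must be strictly below max for each component")
  }
  out <- sweep(scores, 2, minmax[, "min"])
  out <- sweep(out, 2, minmax[, "max"] - minmax[, "min"], "/")
  clamp01(out)
}

#' Project cube pixels into normalized score space
#'
#' @param cube A [reconstruct_cube()] result.
#' @param model A [fit_score_model()] result.
#' @return Tibble with `row`, `col`, `s1`, `s2` (normalized scores).
#' @export
score_pixels <- function(cube, model) {
  Xc <- sweep(cube$spectra, 2, model$center)
  sc <- minmax_normalize(Xc %*% model$loadings, model$minmax)
  tibble::tibble(row = cube$coords$row, col = cube$coords$col,
                 s1 = sc[, 1], s2 = sc[, 2])
}

#' Classify scored pixels into arteries and veins
#'
#' Applies the model's scalar threshold on normalized component 1; the
#' side whose labelled training mean was higher receives that side's
#' class.
#'
#' @param scores Tibble from [score_pixels()].
#' @param model A [fit_score_model()] result.
#' @return The `scores` tibble with a `label` column
#'   (`"artery"`/`"vein"`).
#' @export
classify_pixels <- function(scores, model) {
  high <- scores$s1 >= model$threshold
  is_artery <- if (model$artery_high) high else !high
  dplyr::mutate(scores, label = ifelse(is_artery, "artery", "vein"))
}

#' Classify a whole cube into an artery/vein label map
#'
#' @param cube A [reconstruct_cube()] result.
#' @param model A [fit_score_model()] result.
#' @return Integer label map (0 background, 1 artery, 2 vein) of the
#'   cube's image dimensions.
#' @export
classify_cube <- function(cube, model) {
  cls <- classify_pixels(score_pixels(cube, model), model)
  out <- matrix(AV_BACKGROUND, cube$dim[1], cube$dim[2])
  out[cbind(cls$row, cls$col)] <- ifelse(cls$label == "artery",
                                         AV_ARTERY, AV_VEIN)
  out
}

#' Overlay artery/vein labels on a fundus image
#'
#' Artery pixels are painted pure red, vein pixels pure blue; background
#' pixels are left unchanged.
#'
#' @param img H x W x 3 RGB array.
#' @param labels Integer label map of matching dimensions.
#' @return H x W x 3 RGB array.
#' @export
render_overlay <- function(img, labels) {
  img <- as_rgb_array(img)
  if (!identical(dim(img)[1:2], dim(labels))) stop("shape mismatch")
  out <- img
  a <- labels == AV_ARTERY
  v <- labels == AV_VEIN
  r <- out[, , 1]; g <- out[, , 2]; b <- out[, , 3]
  r[a] <- 1; g[a] <- 0; b[a] <- 0
  r[v] <- 0; g[v] <- 0; b[v] <- 1
  out[, , 1] <- r; out[, , 2] <- g; out[, , 3] <- b
  out
}

#' @export
print.av_score_model <- function(x, ...) {
  cat(sprintf(
    "<av_score_model> stage %s, threshold %.3f (%s), artery on %s side, n = %d\n",
    x$stage %||% "?", x$threshold, x$method,
    if (x$artery_high) "high" else "low", x$n_train))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Tidy an artery/vein score model
#'
#' @param x An `av_score_model`.
#' @param ... Unused.
#' @return Long tibble of loadings: `wavelength`, `component`, `loading`.
#' @export
tidy.av_score_model <- function(x, ...) {
  tibble::tibble(
    wavelength = rep(x$wavelength, 2),
    component = rep(c("PC1", "PC2"), each = length(x$wavelength)),
    loading = c(x$loadings[, 1], x$loadings[, 2])
  )
}

#' One-row summary of an artery/vein score model
#'
#' @param x An `av_score_model`.
#' @param ... Unused.
#' @return One-row tibble with threshold, orientation, variances and n.
#' @export
glance.av_score_model <- function(x, ...) {
  tibble::tibble(stage = x$stage %||% NA_character_,
                 threshold = x$threshold, method = x$method,
                 artery_high = x$artery_high,
                 var_pc1 = x$values[1], var_pc2 = x$values[2],
                 n_train = x$n_train)
}
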
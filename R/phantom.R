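# Synthetic fundus phantom: a dark circular field of view containing a
# branching vessel tree whose artery/vein colours come from the parametric
# reflectance model rendered through the camera model. Stands in for
# clinical fundus photographs so the whole pipeline is testable with known
# ground truth.

# Background / artery / vein label codes used in label maps.
AV_BACKGROUND <- 0L
AV_ARTERY <- 1L
AV_VEIN <- 2L

av_code <- function(class) {
  switch(class, background = AV_BACKGROUND, artery = AV_ARTERY, vein = AV_VEIN,
         stop("unknown class '", class, "'"))
}

# Quadratic Bezier through p0, p1 (control), p2, sampled densely enough
# that consecutive samples are < `step` apart.
bezier_points <- function(p0, p1, p2, step = 0.35) {
  chord <- sqrt(sum((p2 - p0)^2)) + sqrt(sum((p1 - p0)^2)) +
    sqrt(sum((p2 - p1)^2))
  n <- max(8L, ceiling(chord / step))
  t <- seq(0, 1, length.out = n)
  cbind((1 - t)^2 * p0[1] + 2 * (1 - t) * t * p1[1] + t^2 * p2[1],
        (1 - t)^2 * p0[2] + 2 * (1 - t) * t * p1[2] + t^2 * p2[2])
}

# Stamp one curve into per-class softness/halfwidth accumulators.
# soft: max over curves of a flat-top profile (1 inside the lumen,
# Gaussian falloff at the wall); pixels with distance <= halfwidth get
# exactly 1, which makes noiseless vessel colours exact.
stamp_curve <- function(soft, pts, halfwidth, edge_sd = 0.7) {
  H <- nrow(soft); W <- ncol(soft)
  r <- ceiling(halfwidth + 3 * edge_sd)
  off <- seq(-r, r)
  for (i in seq_len(nrow(pts))) {
    pr <- pts[i, 1]; pc <- pts[i, 2]
    rows <- round(pr) + off; cols <- round(pc) + off
    rok <- rows >= 1 & rows <= H; cok <- cols >= 1 & cols <= W
    if (!any(rok) || !any(cok)) next
    rows <- rows[rok]; cols <- cols[cok]
    d <- sqrt(outer((rows - pr)^2, (cols - pc)^2, "+"))
    prof <- ifelse(d <= halfwidth, 1, exp(-0.5 * ((d - halfwidth) / edge_sd)^2))
    blk <- soft[rows, cols, drop = FALSE]
    soft[rows, cols] <- pmax(blk, prof)
  }
  soft
}

# Random branching tree of quadratic Bezier segments radiating from an
# optic-disc-like origin to the FOV boundary. Returns a list of
# (points, halfwidth) segments. Must be called inside with_seed().
grow_tree <- function(n_main, center, fov_radius, origin, halfwidth_range,
                      branch_prob = 0.7) {
  segs <- list()
  angles <- seq(0, 2 * pi, length.out = n_main + 1)[-1] +
    stats::runif(n_main, -0.25, 0.25)
  for (a in angles) {
    hw <- stats::runif(1, halfwidth_range[1], halfwidth_range[2])
    end <- center + 0.96 * fov_radius * c(sin(a), cos(a))
    mid <- (origin + end) / 2
    perp <- c(cos(a), -sin(a)) * stats::runif(1, -0.25, 0.25) * fov_radius
    ctrl <- mid + perp
    pts <- bezier_points(origin, ctrl, end)
    segs[[length(segs) + 1]] <- list(points = pts, halfwidth = hw)
    if (stats::runif(1) < branch_prob) {
      t0 <- stats::runif(1, 0.35, 0.7)
      i0 <- max(2L, ceiling(t0 * nrow(pts)))
      b0 <- pts[i0, ]
      ba <- a + stats::runif(1, 0.4, 0.9) * sample(c(-1, 1), 1)
      bend <- center + 0.9 * fov_radius * c(sin(ba), cos(ba))
      bctrl <- (b0 + bend) / 2 + c(cos(ba), -sin(ba)) *
        stats::runif(1, -0.15, 0.15) * fov_radius
      segs[[length(segs) + 1]] <- list(points = bezier_points(b0, bctrl, bend),
                                       halfwidth = 0.75 * hw)
    }
  }
  segs
}

#' Generate a synthetic fundus phantom
#'
#' Builds a square RGB fundus-like scene: a dark circular field of view
#' (FOV) on a black frame, a branching tree of arteries and veins drawn as
#' quadratic Bezier curves with Gaussian-walled cross sections, coloured
#' by rendering the stage's artery/vein reflectance spectra through the
#' camera model. Veins are drawn wider (by `vein_width_factor`) and, by
#' construction of the spectral model, darker than arteries. Ground-truth
#' vessel mask, artery/vein label map, FOV mask and the true class spectra
#' are returned alongside the image. Additive i.i.d. Gaussian RGB noise
#' (clamped to \[0, 1\]) emulates sensor noise.
#'
#' @param stage Severity stage name (see [severity_levels()]).
#' @param size Image side in pixels (>= 128).
#' @param cam A [camera_model()].
#' @param params A [spectral_params()] list.
#' @param noise_sd Standard deviation of the additive RGB noise.
#' @param seed Integer seed; the scene is a pure function of it.
#' @param n_arteries,n_veins Number of main vessels per class.
#' @param artery_halfwidth Range (px) of arterial half-widths; full vessel
#'   widths stay within the 2--12 px regime the segmenter is tuned to.
#' @param vein_width_factor Vein half-width multiplier.
#' @param fov_radius_frac FOV radius as a fraction of the image side.
#' @param max_coverage Error if the vessel mask would exceed this fraction
#'   of the FOV (guards against degenerate density settings).
#' @return A list of class `phantom_scene` with elements `image`
#'   (size x size x 3, values in \[0, 1\]), `vessel_mask`, `av_labels`
#'   (0 = background, 1 = artery, 2 = vein), `fov_mask`, `spectra` (tibble
#'   from [av_spectra()]), `camera`, `stage`, `contrast_scale`,
#'   `noise_sd`, `seed`.
#' @export
#' @examples
#' sc <- phantom_fundus("normal", size = 128, seed = 7)
#' mean(sc$vessel_mask[sc$fov_mask])
phantom_fundus <- function(stage = "normal", size = 256,
                           cam = camera_model(), params = spectral_params(),
                           noise_sd = 0.01, seed = 1,
                           n_arteries = 4, n_veins = 4,
                           artery_halfwidth = c(1.2, 2.6),
                           vein_width_factor = 1.5,
                           fov_radius_frac = 0.46,
                           max_coverage = 0.5) {
  if (size < 128) stop("image size must be at least 128")
  sp <- av_spectra(stage, params, wavelength = cam$wavelength)
  col_art <- camera_response(sp$artery, cam)
  col_vein <- camera_response(sp$vein, cam)
  col_bg <- camera_response(sp$background, cam)

  center <- c((size + 1) / 2, (size + 1) / 2)
  radius <- fov_radius_frac * size
  rr <- matrix(seq_len(size), size, size)
  cc <- t(rr)
  fov <- (rr - center[1])^2 + (cc - center[2])^2 <= radius^2

  scene <- with_seed(seed, {
    disc_angle <- stats::runif(1, 0, 2 * pi)
    origin <- center + 0.35 * radius * c(sin(disc_angle), cos(disc_angle))
    segs_a <- grow_tree(n_arteries, center, radius, origin, artery_halfwidth)
    segs_v <- grow_tree(n_veins, center, radius, origin,
                        artery_halfwidth * vein_width_factor)
    soft_a <- matrix(0, size, size)
    soft_v <- matrix(0, size, size)
    for (s in segs_a) soft_a <- stamp_curve(soft_a, s$points, s$halfwidth)
    for (s in segs_v) soft_v <- stamp_curve(soft_v, s$points, s$halfwidth)
    noise <- if (noise_sd > 0) {
      array(stats::rnorm(size * size * 3, sd = noise_sd), c(size, size, 3))
    } else {
      array(0, c(size, size, 3))
    }
    list(soft_a = soft_a, soft_v = soft_v, noise = noise)
  })

  soft_a <- scene$soft_a * fov
  soft_v <- scene$soft_v * fov
  artery_px <- soft_a >= 1 & soft_a >= soft_v
  vein_px <- soft_v >= 1 & soft_v > soft_a
  vessel_mask <- artery_px | vein_px
  labels <- matrix(AV_BACKGROUND, size, size)
  labels[artery_px] <- AV_ARTERY
  labels[vein_px] <- AV_VEIN

  coverage <- sum(vessel_mask) / sum(fov)
  if (coverage > max_coverage) {
    stop(sprintf("vessel coverage %.1f%% exceeds %.0f%% of the FOV",
                 100 * coverage, 100 * max_coverage))
  }

  # Compose colours: per-pixel blend weight is the strongest class profile;
  # lumen pixels (profile == 1) get the exact class colour.
  w <- pmax(soft_a, soft_v)
  use_art <- soft_a >= soft_v
  img <- array(0, c(size, size, 3))
  for (ch in 1:3) {
    vessel_col <- ifelse(use_art, col_art[ch], col_vein[ch])
    plane <- col_bg[ch] * (1 - w) + vessel_col * w
    plane[!fov] <- 0
    img[, , ch] <- plane
  }
  img <- clamp01(img + scene$noise * rep(fov, 3))

  structure(list(image = img, vessel_mask = vessel_mask, av_labels = labels,
                 fov_mask = fov, spectra = sp, camera = cam, stage = stage,
                 contrast_scale = if (stage %in% severity_levels()$stage)
                   contrast_scale_for(stage) else NA_real_,
                 params = params, noise_sd = noise_sd, seed = seed),
            class = "phantom_scene")
}

#' @export
print.phantom_scene <- function(x, ...) {
  cat(sprintf(
    "<phantom_scene> %dx%d, stage %s, %d vessel px (%.1f%% of FOV), seed %d\n",
    nrow(x$vessel_mask), ncol(x$vessel_mask), x$stage, sum(x$vessel_mask),
    100 * sum(x$vessel_mask) / sum(x$fov_mask), x$seed))
  invisible(x)
}
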
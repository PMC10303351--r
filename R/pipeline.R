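# End-to-end orchestration: configuration, image-level train/test
# splitting, the per-stage artery/vein experiment, and the full pipeline
# run with artifact persistence.

#' Seeded train/test split
#'
#' Shuffles the items with the given seed and assigns `round(fraction * n)`
#' of them to the test set; the split is disjoint and exhaustive. Items
#' are split at the image level to avoid pixel leakage between sets.
#'
#' @param items Vector or list to split.
#' @param fraction Test fraction in (0, 1); default 0.30.
#' @param seed Integer seed.
#' @return List with `train` and `test`.
#' @export
split_train_test <- function(items, fraction = 0.30, seed = 1) {
  n <- length(items)
  if (n < 2) stop("need at least 2 items to split")
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  n_test <- round(fraction * n)
  perm <- with_seed(seed, sample.int(n))
  test_idx <- sort(perm[seq_len(n_test)])
  train_idx <- sort(perm[setdiff(seq_len(n), seq_len(n_test))])
  list(train = items[train_idx], test = items[test_idx])
}

#' Pipeline run configuration
#'
#' Collects every tunable parameter of the pipeline in one serializable
#' list. Defaults reproduce the standard study conditions: 256 px
#' phantoms, 1 nm grid, RGB noise sd 0.01, a 30% test split, 181-angle
#' Gabor bank, ridge 1e-6, midpoint threshold.
#'
#' @param stages Stage names to run.
#' @param n_images Phantom images per stage.
#' @param image_size Phantom side length in px.
#' @param noise_sd Additive RGB noise sd.
#' @param split_fraction Test fraction.
#' @param seed Master seed; all per-image and checker seeds derive from it.
#' @param checker_seed Seed of the synthetic color checker.
#' @param grid_step Wavelength step (nm).
#' @param k Number of basis eigenvectors.
#' @param ridge Calibration ridge regularizer.
#' @param threshold_method `"midpoint"` or `"f1_scan"`.
#' @param f0,sigma_x,sigma_y,theta_step Gabor bank parameters.
#' @param epsilon Iterative-threshold tolerance (0--255 gray levels).
#' @param min_pixels Small-object removal size.
#' @param mask_source `"truth"` evaluates A/V classification on the
#'   ground-truth vessel mask (segmentation quality is reported
#'   separately as Dice); `"predicted"` uses the segmented mask.
#' @param segment Run the segmentation stage (Dice per image).
#' @param out_dir Optional output directory for artifacts.
#' @return A list of class `run_config`.
#' @export
run_config <- function(stages = severity_levels()$stage, n_images = 10,
                       image_size = 256, noise_sd = 0.01,
                       split_fraction = 0.30, seed = 1, checker_seed = NULL,
                       grid_step = 1, k = 6, ridge = 1e-6,
                       threshold_method = "midpoint",
                       f0 = 1 / 8, sigma_x = 1.5, sigma_y = 3,
                       theta_step = pi / 180, epsilon = 1e-3,
                       min_pixels = 30, mask_source = c("truth", "predicted"),
                       segment = TRUE, out_dir = NULL) {
  mask_source <- match.arg(mask_source)
  if (is.null(checker_seed)) checker_seed <- derive_seed(seed, 999)
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

#' Save / load a run configuration as YAML
#'
#' @param cfg A [run_config()].
#' @param path YAML file.
#' @return `save_config()` returns the path invisibly; `load_config()`
#'   returns a `run_config` equal to the saved one (unset optional fields
#'   fall back to defaults).
#' @export
save_config <- function(cfg, path) {
  obj <- unclass(cfg)
  obj <- obj[!vapply(obj, is.null, logical(1))]
  yaml::write_yaml(obj, path, precision = 15)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  vals <- yaml::read_yaml(path)
  cfg <- run_config()
  for (nm in names(vals)) cfg[[nm]] <- vals[[nm]]
  class(cfg) <- "run_config"
  cfg
}

config_camera <- function(cfg) {
  camera_model(wavelength = wavelength_grid(step = cfg$grid_step))
}

config_gabor <- function(cfg) {
  gabor_params(f0 = cfg$f0, sigma_x = cfg$sigma_x, sigma_y = cfg$sigma_y,
               theta_step = cfg$theta_step)
}

#' Per-stage artery/vein classification experiment
#'
#' For each stage and replicate seed: simulate `n_images` phantoms, split
#' them 70/30 into training and test images, calibrate the RGB-to-spectrum
#' transformation on a synthetic color checker, reconstruct vessel-pixel
#' spectra, fit the stage's score model on the pooled training pixels and
#' classify the pooled test pixels. Metrics are computed per stage and
#' replicate over the pooled test-image confusion counts.
#'
#' @param cfg A [run_config()].
#' @param n_seeds Number of replicate runs per stage.
#' @return Tibble with `replicate`, `stage`, `class`, `sensitivity`,
#'   `precision`, `f1`, `tp`, `fp`, `fn` (percent, unrounded).
#' @export
run_av_experiment <- function(cfg = run_config(), n_seeds = 1) {
  cam <- config_camera(cfg)
  checker <- color_checker(cam, seed = cfg$checker_seed)
  basis <- fit_spectral_basis(checker, k = cfg$k)
  tm <- fit_transformation(checker, basis, ridge = cfg$ridge)
  rows <- list()
  for (rep_i in seq_len(n_seeds)) {
    for (stage in cfg$stages) {
      stage_off <- match(stage, severity_levels()$stage)
      scenes <- lapply(seq_len(cfg$n_images), function(i) {
        phantom_fundus(stage, size = cfg$image_size, cam = cam,
                       noise_sd = cfg$noise_sd,
                       seed = derive_seed(cfg$seed,
                                          rep_i * 10000 + stage_off * 100 + i))
      })
      sp <- split_train_test(scenes, fraction = cfg$split_fraction,
                             seed = derive_seed(cfg$seed, rep_i))
      cube_of <- function(scene) {
        reconstruct_cube(scene$image, scene$vessel_mask, tm)
      }
      train_cubes <- lapply(sp$train, cube_of)
      train_cube <- bind_cubes(train_cubes)
      train_labels <- unlist(lapply(seq_along(sp$train), function(j) {
        cube_labels(train_cubes[[j]], sp$train[[j]]$av_labels)
      }), use.names = FALSE)
      model <- fit_score_model_vec(train_cube, train_labels, stage = stage,
                                   method = cfg$threshold_method)
      m <- dplyr::bind_rows(lapply(sp$test, function(scene) {
        cube <- cube_of(scene)
        pred <- classify_cube(cube, model)
        av_metrics_counts_only(pred, scene$av_labels)
      }))
      pooled <- dplyr::summarise(dplyr::group_by(m, .data$class),
                                 tp = sum(.data$tp), fp = sum(.data$fp),
                                 fn = sum(.data$fn), .groups = "drop")
      pooled <- dplyr::mutate(
        pooled, replicate = rep_i, stage = stage,
        sensitivity = 100 * .data$tp / (.data$tp + .data$fn),
        precision = 100 * .data$tp / (.data$tp + .data$fp),
        f1 = f1_score(.data$sensitivity, .data$precision))
      rows[[length(rows) + 1]] <- pooled
    }
  }
  out <- dplyr::bind_rows(rows)
  dplyr::select(out, "replicate", "stage", "class", "sensitivity",
                "precision", "f1", "tp", "fp", "fn")
}

# concatenate cubes from several images (coordinates lose image identity;
# used only for pooled model fitting)
bind_cubes <- function(cubes) {
  structure(list(
    coords = dplyr::bind_rows(lapply(cubes, function(x) x$coords)),
    spectra = do.call(rbind, lapply(cubes, function(x) x$spectra)),
    wavelength = cubes[[1]]$wavelength,
    dim = cubes[[1]]$dim), class = "spectral_cube")
}

# Variant of fit_score_model taking a per-pixel label vector; pooled
# cubes reuse coordinates across images, so labels cannot be looked up
# through a single label map.
fit_score_model_vec <- function(cube, lab, stage, method) {
  stopifnot(length(lab) == nrow(cube$spectra))
  keep <- lab %in% c(AV_ARTERY, AV_VEIN)
  X <- cube$spectra[keep, , drop = FALSE]
  lab <- lab[keep]
  pseudo_cube <- structure(list(
    coords = tibble::tibble(row = seq_len(nrow(X)), col = 1L),
    spectra = X, wavelength = cube$wavelength,
    dim = c(nrow(X), 1L)), class = "spectral_cube")
  pseudo_labels <- matrix(AV_BACKGROUND, nrow(X), 1)
  pseudo_labels[, 1] <- lab
  fit_score_model(pseudo_cube, pseudo_labels, stage = stage, method = method)
}

av_metrics_counts_only <- function(pred, truth) {
  dplyr::bind_rows(lapply(c("artery", "vein"), function(cl) {
    confusion_counts(pred, truth, cl)
  }))
}

#' Run the full pipeline on synthetic data
#'
#' Executes simulate, segment (Dice against ground truth), calibrate,
#' reconstruct, classify and evaluate for every configured stage, and
#' optionally persists masks, overlays, the calibration model and the
#' metrics to `cfg$out_dir`. Deterministic given the config seeds.
#'
#' @param cfg A [run_config()].
#' @return A list of class `run_manifest` with `config`, `metrics`
#'   (per-stage table), `trend`, `dice` (per image), `files`, `version`,
#'   `timestamp`.
#' @export
run_pipeline <- function(cfg = run_config()) {
  cam <- config_camera(cfg)
  checker <- color_checker(cam, seed = cfg$checker_seed)
  basis <- fit_spectral_basis(checker, k = cfg$k)
  tm <- fit_transformation(checker, basis, ridge = cfg$ridge)
  gp <- config_gabor(cfg)
  files <- character(0)
  out_dir <- cfg$out_dir
  persist <- !is.null(out_dir)
  if (persist) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  dice_rows <- list()
  preds <- list(); truths <- list(); stages_of <- character(0)
  for (stage in cfg$stages) {
    stage_off <- match(stage, severity_levels()$stage)
    scenes <- lapply(seq_len(cfg$n_images), function(i) {
      phantom_fundus(stage, size = cfg$image_size, cam = cam,
                     noise_sd = cfg$noise_sd,
                     seed = derive_seed(cfg$seed, 10000 + stage_off * 100 + i))
    })
    masks <- lapply(scenes, function(scene) {
      if (!cfg$segment) return(scene$vessel_mask)
      seg <- segment_vessels(scene$image, p = gp, epsilon = cfg$epsilon,
                             min_pixels = cfg$min_pixels,
                             fov = scene$fov_mask)
      seg$mask
    })
    if (cfg$segment) {
      for (i in seq_along(scenes)) {
        dice_rows[[length(dice_rows) + 1]] <- tibble::tibble(
          stage = stage, image = i,
          dice = dice_coefficient(masks[[i]], scenes[[i]]$vessel_mask))
      }
    }
    eval_masks <- if (cfg$mask_source == "truth") {
      lapply(scenes, function(s) s$vessel_mask)
    } else {
      masks
    }
    sp_idx <- split_train_test(seq_along(scenes),
                               fraction = cfg$split_fraction, seed = cfg$seed)
    cubes <- lapply(seq_along(scenes), function(i) {
      reconstruct_cube(scenes[[i]]$image, eval_masks[[i]], tm)
    })
    labels_vec <- function(i) cube_labels(cubes[[i]], scenes[[i]]$av_labels)
    train_cube <- bind_cubes(cubes[sp_idx$train])
    train_lab <- unlist(lapply(sp_idx$train, labels_vec), use.names = FALSE)
    model <- fit_score_model_vec(train_cube, train_lab, stage,
                                 cfg$threshold_method)
    for (i in sp_idx$test) {
      pred <- classify_cube(cubes[[i]], model)
      preds[[length(preds) + 1]] <- pred
      truths[[length(truths) + 1]] <- scenes[[i]]$av_labels
      stages_of <- c(stages_of, stage)
      if (persist) {
        f <- file.path(out_dir, sprintf("%s_test%02d_overlay.png", stage, i))
        write_image_png(render_overlay(scenes[[i]]$image, pred), f)
        files <- c(files, f)
      }
    }
    if (persist) {
      f <- file.path(out_dir, sprintf("%s_score_model.json", stage))
      write_score_model_json(model, f)
      files <- c(files, f)
    }
  }
  metrics <- metrics_table(preds, truths, stages_of)
  trend <- if (all(severity_levels()$stage %in% metrics$stage)) {
    stage_trend(metrics)
  } else {
    NULL
  }
  dice <- dplyr::bind_rows(dice_rows)
  if (persist) {
    f <- file.path(out_dir, "calibration_model.json")
    write_model_json(tm, f)
    files <- c(files, f)
    f <- file.path(out_dir, "metrics.csv")
    utils::write.csv(metrics, f, row.names = FALSE)
    files <- c(files, f)
  }
  structure(list(config = cfg, metrics = metrics, trend = trend,
                 dice = dice, files = files,
                 version = as.character(utils::packageVersion("fundushsi")),
                 timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
            class = "run_manifest")
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("<run_manifest> fundushsi %s, %d stages, %d artifact file(s)\n",
              x$version, length(unique(x$metrics$stage)), length(x$files)))
  print(x$metrics)
  invisible(x)
}
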
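# Pixel-level evaluation of artery/vein classification: per-class
# confusion counts restricted to ground-truth vessel pixels, sensitivity,
# precision, F1, the per-stage report table and the severity-trend
# summary.

#' Per-class confusion counts over ground-truth vessel pixels
#'
#' Comparison is restricted to pixels that are vessels in the truth map
#' (the denominators count the original artery/vein pixels of the image);
#' background pixels never enter the counts.
#'
#' @param pred,truth Integer label maps (0 background, 1 artery, 2 vein)
#'   of equal dimensions.
#' @param class `"artery"` or `"vein"`.
#' @return One-row tibble with `class`, `tp`, `fp`, `fn`, `tn`.
#' @export
confusion_counts <- function(pred, truth, class = "artery") {
  if (!identical(dim(pred), dim(truth))) stop("shape mismatch")
  code <- av_code(class)
  vess <- truth != AV_BACKGROUND
  p <- pred[vess]; t <- truth[vess]
  tibble::tibble(class = class,
                 tp = sum(p == code & t == code),
                 fp = sum(p == code & t != code),
                 fn = sum(p != code & t == code),
                 tn = sum(p != code & t != code))
}

#' Sensitivity (true positive rate), in percent
#'
#' `100 * tp / (tp + fn)`.
#'
#' @param counts A row from [confusion_counts()] (or any list with
#'   `tp`, `fn`).
#' @return Percentage in \[0, 100\].
#' @export
sensitivity <- function(counts) {
  if (counts$tp + counts$fn == 0) stop("no ground-truth positives")
  100 * counts$tp / (counts$tp + counts$fn)
}

#' Precision (positive predictive value), in percent
#'
#' `100 * tp / (tp + fp)`.
#'
#' @param counts A row from [confusion_counts()] (or any list with
#'   `tp`, `fp`).
#' @return Percentage in \[0, 100\].
#' @export
precision <- function(counts) {
  if (counts$tp + counts$fp == 0) stop("no predicted positives")
  100 * counts$tp / (counts$tp + counts$fp)
}

#' F1 score from sensitivity and precision, in percent
#'
#' The harmonic mean `2 * S * P / (S + P)`.
#'
#' @param sensitivity,precision Percentages.
#' @return Percentage between `min` and `max` of the two inputs.
#' @export
#' @examples
#' f1_score(82.4, 88.4) # ~85.3
f1_score <- function(sensitivity, precision) {
  if (any(sensitivity + precision == 0)) {
    stop("sensitivity and precision both zero")
  }
  2 * sensitivity * precision / (sensitivity + precision)
}

#' Per-class metrics for one prediction/truth pair
#'
#' @param pred,truth Integer label maps.
#' @param stage Optional stage name attached to the rows.
#' @return Tibble with one row per class: `stage`, `class`,
#'   `sensitivity`, `precision`, `f1` (unrounded percent), `tp`, `fp`,
#'   `fn`.
#' @export
av_metrics <- function(pred, truth, stage = NA_character_) {
  dplyr::bind_rows(lapply(c("artery", "vein"), function(cl) {
    cc <- confusion_counts(pred, truth, cl)
    s <- sensitivity(cc); p <- precision(cc)
    tibble::tibble(stage = stage, class = cl, sensitivity = s,
                   precision = p, f1 = f1_score(s, p),
                   tp = cc$tp, fp = cc$fp, fn = cc$fn)
  }))
}

#' Per-stage metrics report table
#'
#' Pools confusion counts over the images of each stage and reports
#' sensitivity, precision and F1 per stage and class, rounded to one
#' decimal place.
#'
#' @param preds,truths Lists of label maps (same length).
#' @param stages Character vector of stage names, one per image.
#' @return Tibble with `stage`, `class`, `sensitivity`, `precision`,
#'   `f1`, `tp`, `fp`, `fn`.
#' @export
metrics_table <- function(preds, truths, stages) {
  if (!is.list(preds)) preds <- list(preds)
  if (!is.list(truths)) truths <- list(truths)
  stopifnot(length(preds) == length(truths),
            length(stages) == length(preds), length(preds) >= 1)
  counts <- dplyr::bind_rows(lapply(seq_along(preds), function(i) {
    dplyr::bind_rows(lapply(c("artery", "vein"), function(cl) {
      dplyr::mutate(confusion_counts(preds[[i]], truths[[i]], cl),
                    stage = stages[i])
    }))
  }))
  pooled <- dplyr::summarise(
    dplyr::group_by(counts, .data$stage, .data$class),
    tp = sum(.data$tp), fp = sum(.data$fp), fn = sum(.data$fn),
    .groups = "drop")
  out <- dplyr::mutate(
    pooled,
    sensitivity = round(100 * .data$tp / (.data$tp + .data$fn), 1),
    precision = round(100 * .data$tp / (.data$tp + .data$fp), 1),
    f1 = round(f1_score(100 * .data$tp / (.data$tp + .data$fn),
                        100 * .data$tp / (.data$tp + .data$fp)), 1))
  stage_order <- intersect(c(severity_levels()$stage, unique(out$stage)),
                           unique(out$stage))
  out <- out[order(match(out$stage, stage_order), out$class), ]
  dplyr::select(out, "stage", "class", "sensitivity", "precision", "f1",
                "tp", "fp", "fn")
}

#' Severity-trend summary of a metrics table
#'
#' For each class and indicator, reports whether the normal stage is
#' strictly maximal and PDR strictly minimal across the four stages, and
#' the Spearman correlation between the stage contrast scales and the
#' metric values.
#'
#' @param metrics Tibble with `stage`, `class` and metric columns
#'   (`sensitivity`, `precision`, `f1`), all four stages present.
#' @return Tibble with `class`, `metric`, `normal_highest`,
#'   `pdr_lowest`, `spearman`, `satisfied`.
#' @export
safe_spearman <- function(x, y) {
  if (stats::sd(y) == 0 || stats::sd(x) == 0) return(NA_real_)
  stats::cor(x, y, method = "spearman")
}

stage_trend <- function(metrics) {
  lev <- severity_levels()
  missing <- setdiff(lev$stage, unique(metrics$stage))
  if (length(missing) > 0) {
    stop("missing stage(s): ", paste(missing, collapse = ", "))
  }
  long <- tidyr::pivot_longer(
    dplyr::select(metrics, "stage", "class", "sensitivity", "precision", "f1"),
    cols = c("sensitivity", "precision", "f1"),
    names_to = "metric", values_to = "value")
  # average replicate rows (e.g. per-seed runs) within each stage first
  long <- dplyr::summarise(
    dplyr::group_by(long, .data$stage, .data$class, .data$metric),
    value = mean(.data$value), .groups = "drop")
  long <- dplyr::left_join(long, lev, by = "stage")
  dplyr::summarise(
    dplyr::group_by(long, .data$class, .data$metric),
    normal_highest = all(.data$value[.data$stage == "normal"] >
                           .data$value[.data$stage != "normal"]),
    pdr_lowest = all(.data$value[.data$stage == "PDR"] <
                       .data$value[.data$stage != "PDR"]),
    spearman = safe_spearman(.data$contrast_scale, .data$value),
    satisfied = .data$normal_highest & .data$pdr_lowest,
    .groups = "drop")
}
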
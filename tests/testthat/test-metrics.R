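random_label_map <- function(n = 10, p_bg = 0.3) {
  matrix(sample(0:2, n * n, replace = TRUE,
                prob = c(p_bg, (1 - p_bg) / 2, (1 - p_bg) / 2)), n, n)
}

test_that("perfect and anti-perfect predictions give the expected counts", {
  set.seed(16)
  truth <- random_label_map()
  cc <- confusion_counts(truth, truth, "artery")
  expect_equal(cc$fp, 0)
  expect_equal(cc$fn, 0)
  expect_equal(cc$tp, sum(truth == 1L))
  swapped <- truth
  swapped[truth == 1L] <- 2L
  swapped[truth == 2L] <- 1L
  for (cl in c("artery", "vein")) {
    expect_equal(confusion_counts(swapped, truth, cl)$tp, 0)
  }
  expect_error(confusion_counts(truth, truth[1:5, 1:5], "artery"),
               "mismatch")
})

test_that("confusion counts match a per-pixel loop oracle", {
  set.seed(17)
  for (i in 1:5) {
    pred <- random_label_map()
    truth <- random_label_map()
    for (cl in c("artery", "vein")) {
      cc <- confusion_counts(pred, truth, cl)
      oracle <- confusion_loop_oracle(pred, truth, fundushsi:::av_code(cl))
      expect_equal(c(tp = cc$tp, fp = cc$fp, fn = cc$fn, tn = cc$tn),
                   oracle)
      # conservation: tp + fn equals the truth map's class pixel count
      expect_equal(cc$tp + cc$fn, sum(truth == fundushsi:::av_code(cl)))
    }
  }
})

test_that("metrics are invariant to relabelling background pixels", {
  set.seed(18)
  pred <- random_label_map()
  truth <- random_label_map()
  pred2 <- pred
  pred2[truth == 0L] <- sample(0:2, sum(truth == 0L), replace = TRUE)
  for (cl in c("artery", "vein")) {
    expect_identical(confusion_counts(pred, truth, cl),
                     confusion_counts(pred2, truth, cl))
  }
})

test_that("sensitivity, precision and F1 follow their formulas", {
  expect_equal(sensitivity(list(tp = 9, fn = 1)), 90)
  expect_equal(sensitivity(list(tp = 5, fn = 0)), 100)
  expect_equal(sensitivity(list(tp = 824, fn = 176)), 82.4)
  expect_error(sensitivity(list(tp = 0, fn = 0)), "positives")
  expect_equal(precision(list(tp = 4, fp = 1)), 80)
  expect_equal(precision(list(tp = 3, fp = 0)), 100)
  expect_equal(precision(list(tp = 884, fp = 116)), 88.4)
  expect_error(precision(list(tp = 0, fp = 0)), "positives")
  expect_error(f1_score(0, 0), "zero")
})

test_that("worked confusion examples reproduce the reported indicator rows", {
  s_a <- sensitivity(list(tp = 824, fn = 176))
  p_a <- precision(list(tp = 884, fp = 116))
  expect_equal(f1_score(s_a, p_a), 85.3, tolerance = 0.05 / 85.3)
  expect_equal(f1_score(88.5, 82.6), 85.4, tolerance = 0.05 / 85.4)
})

test_that("F1 is a symmetric harmonic mean between its arguments", {
  set.seed(19)
  for (i in 1:50) {
    s <- stats::runif(1, 1, 100); p <- stats::runif(1, 1, 100)
    f <- f1_score(s, p)
    expect_equal(f, f1_score(p, s))
    expect_gte(f, min(s, p) - 1e-12)
    expect_lte(f, max(s, p) + 1e-12)
  }
  expect_equal(f1_score(73.5, 73.5), 73.5)
})

test_that("the report table pools counts and stays internally consistent", {
  set.seed(20)
  truth <- random_label_map(20)
  tab <- metrics_table(list(truth), list(truth), "normal")
  expect_equal(tab$sensitivity, c(100, 100))
  expect_equal(tab$f1, c(100, 100))
  pred <- random_label_map(20)
  tab2 <- metrics_table(list(pred, pred), list(truth, truth),
                        c("normal", "normal"))
  for (i in seq_len(nrow(tab2))) {
    expect_equal(tab2$f1[i],
                 round(f1_score(100 * tab2$tp[i] / (tab2$tp[i] + tab2$fn[i]),
                                100 * tab2$tp[i] / (tab2$tp[i] + tab2$fp[i])),
                       1),
                 tolerance = 0.051)
  }
})

test_that("the published per-stage table satisfies the severity trend", {
  reported <- tibble::tibble(
    stage = rep(c("normal", "BDR", "PPDR", "PDR"), 2),
    class = rep(c("artery", "vein"), each = 4),
    sensitivity = c(82.4, 77.5, 78.1, 72.9, 88.5, 85.4, 81.4, 75.1),
    precision = c(88.4, 83.5, 80.7, 73.4, 82.6, 81.2, 79.2, 74.6),
    f1 = c(85.3, 80.3, 79.4, 73.1, 85.4, 83.2, 80.3, 74.8))
  tr <- stage_trend(reported)
  expect_equal(nrow(tr), 6)
  expect_true(all(tr$normal_highest))
  expect_true(all(tr$pdr_lowest))
  expect_true(all(tr$satisfied))
})

test_that("a flat metrics profile does not satisfy the trend", {
  flat <- tibble::tibble(
    stage = rep(c("normal", "BDR", "PPDR", "PDR"), 2),
    class = rep(c("artery", "vein"), each = 4),
    sensitivity = 80, precision = 80, f1 = 80)
  tr <- stage_trend(flat)
  expect_false(any(tr$satisfied))
  expect_error(stage_trend(flat[flat$stage != "PDR", ]), "missing stage")
})
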
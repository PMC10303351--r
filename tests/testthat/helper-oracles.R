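# Independent brute-force oracles used to validate the fast
# implementations. These deliberately share no code with the package
# internals.

# Naive four-loop spatial correlation with reflection padding.
naive_correlation <- function(img, kernel) {
  h <- (nrow(kernel) - 1L) %/% 2L
  H <- nrow(img); W <- ncol(img)
  pad <- img[c(h:1, 1:H, H:(H - h + 1L)), c(h:1, 1:W, W:(W - h + 1L))]
  out <- matrix(0, H, W)
  for (r in seq_len(H)) {
    for (cc in seq_len(W)) {
      acc <- 0
      for (i in seq_len(2 * h + 1)) {
        for (j in seq_len(2 * h + 1)) {
          acc <- acc + pad[r + i - 1L, cc + j - 1L] * kernel[i, j]
        }
      }
      out[r, cc] <- acc
    }
  }
  out
}

# Brute-force fixed-point scan for the iterative-mean threshold: evaluate
# g(T) = (mean below + mean above) / 2 at every 8-bit gray level and keep
# the exact fixed points of the piecewise-constant map g.
threshold_fixed_points <- function(x) {
  g <- function(t) {
    lo <- x[x <= t]; hi <- x[x > t]
    if (length(lo) == 0 || length(hi) == 0) return(NA_real_)
    (mean(lo) + mean(hi)) / 2
  }
  cand <- unique(stats::na.omit(vapply(0:255, g, numeric(1))))
  cand[vapply(cand, function(t) {
    gt <- g(t)
    !is.na(gt) && abs(gt - t) < 1e-9
  }, logical(1))]
}

# Recursive-free flood-fill labelling oracle (scan-and-grow with an
# explicit stack, one pixel at a time).
floodfill_labels <- function(mask, connectivity = 8) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  cur <- 0L
  neigh <- if (connectivity == 8) {
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  }
  for (r0 in seq_len(H)) {
    for (c0 in seq_len(W)) {
      if (!mask[r0, c0] || lab[r0, c0] != 0L) next
      cur <- cur + 1L
      stack <- list(c(r0, c0))
      lab[r0, c0] <- cur
      while (length(stack) > 0) {
        p <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        for (k in seq_len(nrow(neigh))) {
          r <- p[1] + neigh[k, 1]; cc <- p[2] + neigh[k, 2]
          if (r >= 1 && r <= H && cc >= 1 && cc <= W &&
              mask[r, cc] && lab[r, cc] == 0L) {
            lab[r, cc] <- cur
            stack[[length(stack) + 1]] <- c(r, cc)
          }
        }
      }
    }
  }
  lab
}

# Per-pixel loop oracle for confusion counts restricted to truth vessels.
confusion_loop_oracle <- function(pred, truth, code) {
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_along(pred)) {
    if (truth[i] == 0L) next
    if (pred[i] == code && truth[i] == code) tp <- tp + 1L
    else if (pred[i] == code && truth[i] != code) fp <- fp + 1L
    else if (pred[i] != code && truth[i] == code) fn <- fn + 1L
    else tn <- tn + 1L
  }
  c(tp = tp, fp = fp, fn = fn, tn = tn)
}
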
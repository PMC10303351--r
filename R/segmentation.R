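# Vessel segmentation: green-channel extraction, iterative-mean
# binarization of the Gabor response map, and small-object removal,
# restricted to the circular field of view.

#' Extract the green channel of an RGB image
#'
#' The green component carries the strongest vessel/background contrast in
#' fundus photographs and is the input to the Gabor bank.
#'
#' @param img H x W x 3 RGB array.
#' @return H x W numeric matrix, values unchanged in scale.
#' @export
extract_green <- function(img) {
  img <- as_rgb_array(img)
  img[, , 2]
}

#' Iterative-mean threshold selection
#'
#' The classic iterative scheme: start from the mean gray value of all
#' pixels, split the pixels at the current threshold, and replace the
#' threshold by the average of the two group means, repeating until the
#' change falls below `epsilon`. Ties (value equal to the threshold) are
#' assigned to the low group. A flat input is degenerate and returns its
#' common value with zero iterations.
#'
#' @param x Numeric vector or matrix of gray values (any scale).
#' @param epsilon Convergence tolerance in gray levels; the default 1e-3
#'   effectively iterates the piecewise-constant update to its exact
#'   fixed point (finite convergence on discrete data).
#' @param max_iter Iteration cap.
#' @return A list of class `threshold_result` with `threshold`,
#'   `iterations`, `history` (per-iteration thresholds, starting with the
#'   initial mean), `converged` and `degenerate`.
#' @export
#' @examples
#' iterative_threshold(c(0, 0, 0, 255, 255, 255))$threshold # 127.5
iterative_threshold <- function(x, epsilon = 1e-3, max_iter = 100) {
  x <- as.numeric(x)
  x <- x[is.finite(x)]
  if (length(x) == 0) stop("no finite values to threshold")
  if (max(x) == min(x)) {
    return(structure(list(threshold = x[1], iterations = 0L,
                          history = x[1], converged = TRUE,
                          degenerate = TRUE),
                     class = "threshold_result"))
  }
  t_cur <- mean(x)
  history <- t_cur
  converged <- FALSE
  iterations <- 0L
  for (i in seq_len(max_iter)) {
    low <- x <= t_cur
    t_new <- (mean(x[low]) + mean(x[!low])) / 2
    history <- c(history, t_new)
    iterations <- i
    if (abs(t_new - t_cur) < epsilon) {
      t_cur <- t_new
      converged <- TRUE
      break
    }
    t_cur <- t_new
  }
  structure(list(threshold = t_cur, iterations = iterations,
                 history = history, converged = converged,
                 degenerate = FALSE),
            class = "threshold_result")
}

# Connected-component labelling by vectorised breadth-first flood fill.
# Returns an integer matrix; 0 is background.
label_components <- function(mask, connectivity = 8) {
  if (!connectivity %in% c(4, 8)) stop("connectivity must be 4 or 8")
  H <- nrow(mask); W <- ncol(mask)
  mask <- as.logical(mask)
  dim(mask) <- c(H, W)
  labels <- matrix(0L, H, W)
  todo <- which(mask)
  if (length(todo) == 0) return(labels)
  pending <- mask
  dr <- c(-1L, 1L, 0L, 0L)
  dc <- c(0L, 0L, -1L, 1L)
  if (connectivity == 8) {
    dr <- c(dr, -1L, -1L, 1L, 1L)
    dc <- c(dc, -1L, 1L, -1L, 1L)
  }
  lab <- 0L
  for (s in todo) {
    if (!pending[s]) next
    lab <- lab + 1L
    frontier <- s
    pending[s] <- FALSE
    labels[s] <- lab
    while (length(frontier) > 0) {
      fr <- ((frontier - 1L) %% H) + 1L
      fc <- ((frontier - 1L) %/% H) + 1L
      nxt <- integer(0)
      for (k in seq_along(dr)) {
        nr <- fr + dr[k]; nc <- fc + dc[k]
        ok <- nr >= 1L & nr <= H & nc >= 1L & nc <= W
        if (!any(ok)) next
        ii <- (nc[ok] - 1L) * H + nr[ok]
        ii <- ii[pending[ii]]
        if (length(ii) > 0) {
          pending[ii] <- FALSE
          labels[ii] <- lab
          nxt <- c(nxt, ii)
        }
      }
      frontier <- nxt
    }
  }
  labels
}

#' Remove small connected components from a binary mask
#'
#' Deletes every connected object with fewer than `min_pixels` pixels;
#' no pixel is ever added.
#'
#' @param mask Logical matrix.
#' @param min_pixels Minimum component size to keep (>= 1).
#' @param connectivity 4 or 8 (default 8).
#' @return Logical matrix.
#' @export
remove_small_objects <- function(mask, min_pixels = 30, connectivity = 8) {
  if (min_pixels < 1) stop("min_pixels must be >= 1")
  labels <- label_components(mask, connectivity)
  if (max(labels) == 0) return(labels > 0)
  sizes <- tabulate(labels[labels > 0], nbins = max(labels))
  keep <- which(sizes >= min_pixels)
  out <- matrix(labels %in% keep, nrow(labels), ncol(labels))
  out
}

# Binary dilation / erosion with a disc structuring element, via the same
# FFT correlation machinery as the Gabor bank.
disc_kernel <- function(radius) {
  r <- ceiling(radius)
  off <- seq(-r, r)
  d <- sqrt(outer(off^2, off^2, "+"))
  (d <= radius) * 1
}

binary_dilate <- function(mask, radius) {
  k <- disc_kernel(radius)
  h <- (nrow(k) - 1L) %/% 2L
  pf <- pad_fft(mask * 1, h)
  Re(corr_with_kernel(pf, k)) > 0.5
}

binary_erode <- function(mask, radius) {
  k <- disc_kernel(radius)
  h <- (nrow(k) - 1L) %/% 2L
  pf <- pad_fft(mask * 1, h)
  Re(corr_with_kernel(pf, k)) > sum(k) - 0.5
}

binary_close <- function(mask, radius) {
  binary_erode(binary_dilate(mask, radius), radius)
}

# Fill holes: background components not touching the image border.
fill_holes <- function(mask) {
  bg <- label_components(!mask, connectivity = 4)
  border <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  border <- border[border > 0]
  mask | (bg > 0 & !(bg %in% border))
}

#' Estimate the circular field-of-view mask of a fundus image
#'
#' Keeps the largest connected region whose mean channel intensity exceeds
#' `dark_level`, then morphologically closes it and fills holes. For
#' fundus-like inputs the result is the (roughly circular) illuminated
#' disc.
#'
#' @param img H x W x 3 RGB array.
#' @param dark_level Intensity cutoff separating the frame from the FOV.
#' @param close_radius Radius (px) of the closing disc.
#' @return Logical matrix.
#' @export
estimate_fov_mask <- function(img, dark_level = 0.03, close_radius = 5) {
  img <- as_rgb_array(img)
  intensity <- (img[, , 1] + img[, , 2] + img[, , 3]) / 3
  bright <- intensity > dark_level
  if (!any(bright)) stop("image entirely below dark level")
  labels <- label_components(bright, connectivity = 8)
  sizes <- tabulate(labels[labels > 0], nbins = max(labels))
  fov <- labels == which.max(sizes)
  fill_holes(binary_close(fov, close_radius))
}

#' Segment retinal vessels
#'
#' Full segmentation chain: extract the green channel, run the oriented
#' Gabor bank and keep the per-pixel maximum magnitude response, rescale
#' the response over the field of view to 0--255, binarize it with the
#' iterative-mean threshold (vessels are response maxima, so pixels
#' strictly above the threshold are kept), restrict to the FOV and remove
#' small objects.
#'
#' @param img H x W x 3 RGB array.
#' @param p A [gabor_params()].
#' @param epsilon Convergence tolerance of the iterative threshold
#'   (gray levels on the rescaled 0--255 response).
#' @param min_pixels Small-object removal size.
#' @param fov Optional logical FOV mask; estimated with
#'   [estimate_fov_mask()] when `NULL`.
#' @param dark_level Passed to [estimate_fov_mask()].
#' @return A list of class `vessel_segmentation` with `mask` (logical),
#'   `response` (the max-response map), `threshold`
#'   (a `threshold_result`), `fov`.
#' @export
segment_vessels <- function(img, p = gabor_params(), epsilon = 1e-3,
                            min_pixels = 30, fov = NULL, dark_level = 0.03) {
  img <- as_rgb_array(img)
  gray <- extract_green(img)
  if (is.null(fov)) {
    intensity <- (img[, , 1] + img[, , 2] + img[, , 3]) / 3
    if (!any(intensity > dark_level)) {
      # entirely dark frame: nothing to segment
      empty <- matrix(FALSE, nrow(gray), ncol(gray))
      return(structure(list(mask = empty, response = NULL,
                            threshold = NULL, fov = empty),
                       class = "vessel_segmentation"))
    }
    fov <- estimate_fov_mask(img, dark_level)
  }
  rmap <- max_response_map(gray, p)
  r <- rmap$response
  rv <- r[fov]
  if (length(rv) == 0 || max(rv) == min(rv)) {
    mask <- matrix(FALSE, nrow(gray), ncol(gray))
    thr <- if (length(rv)) iterative_threshold(rv, epsilon) else NULL
    return(structure(list(mask = mask, response = rmap, threshold = thr,
                          fov = fov),
                     class = "vessel_segmentation"))
  }
  r255 <- (r - min(rv)) / (max(rv) - min(rv)) * 255
  thr <- iterative_threshold(r255[fov], epsilon = epsilon)
  mask <- (r255 > thr$threshold) & fov
  mask <- remove_small_objects(mask, min_pixels = min_pixels,
                               connectivity = 8)
  structure(list(mask = mask, response = rmap, threshold = thr, fov = fov),
            class = "vessel_segmentation")
}

#' @export
print.vessel_segmentation <- function(x, ...) {
  cat(sprintf("<vessel_segmentation> %d vessel px", sum(x$mask)))
  if (!is.null(x$threshold)) {
    cat(sprintf(", threshold %.2f (%d iterations)",
                x$threshold$threshold, x$threshold$iterations))
  }
  cat("\n")
  invisible(x)
}
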
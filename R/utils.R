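# Internal helpers shared across modules.

clamp01 <- function(x) pmin(pmax(x, 0), 1)

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so generators are pure functions of their seed argument.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    # initialise RNG state so we have something to restore
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# Derive a child seed from a base seed and an offset, kept within 32-bit range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset * 104729) %% 2147483587)
}

stopifnot_raster <- function(x, name = deparse(substitute(x))) {
  if (!is.matrix(x) || !all(is.finite(x))) {
    stop(sprintf("`%s` must be a finite numeric matrix", name), call. = FALSE)
  }
  invisible(x)
}

# Coerce an RGB image to an H x W x 3 array in [0,1].
as_rgb_array <- function(img) {
  if (is.array(img) && length(dim(img)) == 3 && dim(img)[3] == 3) {
    return(img)
  }
  stop("expected an H x W x 3 RGB array", call. = FALSE)
}

#' Dice similarity coefficient between two binary masks
#'
#' @param a,b Logical matrices of the same dimension.
#' @return A number in \[0, 1\]; two empty masks have Dice 1.
#' @export
dice_coefficient <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  a <- as.logical(a); b <- as.logical(b)
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}
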
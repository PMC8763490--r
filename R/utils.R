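# Shared numeric helpers.

#' Separable Gaussian blur of a matrix
#'
#' Zero-padded separable convolution with a truncated Gaussian kernel
#' (radius `3*sigma`). Used for the sub-pixel roundness perimeter and for
#' the kernel-weighted region intensities of the localized level-set energy.
#'
#' @param m numeric matrix.
#' @param sigma kernel standard deviation in pixels (> 0).
#' @return blurred matrix of the same shape.
#' @export
gaussian_blur <- function(m, sigma) {
  stopifnot(is.matrix(m), is.numeric(sigma), sigma > 0)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  conv_cols <- function(x) {
    xp <- rbind(matrix(0, r, ncol(x)), x, matrix(0, r, ncol(x)))
    out <- apply(xp, 2, function(col) as.numeric(stats::filter(col, k, sides = 2)))
    out <- matrix(out, nrow = nrow(xp))
    out[(r + 1):(r + nrow(x)), , drop = FALSE]
  }
  t(conv_cols(t(conv_cols(m))))
}

#' Dice overlap coefficient between two binary masks
#'
#' `2|A n B| / (|A| + |B|)`; equals 1 for identical non-empty masks. Two
#' empty masks are in perfect agreement and return 1.
#'
#' @param a,b logical arrays of identical shape.
#' @export
dice <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  a <- as.logical(a); b <- as.logical(b)
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}

# run `expr` under a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  expr
}

# derive a stream of child seeds from one seed, staying within 32-bit range
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}
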
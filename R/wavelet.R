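# Daubechies-2 wavelet decimation of virtual slides.
#
# Whole-slide images scanned at ~0.5 um/px are far too large for regional
# statistics; keeping only the approximation (low-pass) band of an
# orthogonal Daubechies wavelet transform halves each dimension per level
# while preserving local mean intensity. Three levels map 0.5 um/px to
# the 4 um/px working resolution at which one pixel is roughly one cell.

# db2 analysis low-pass filter; sums to sqrt(2)
.db2_lo <- c(1 + sqrt(3), 3 + sqrt(3), 3 - sqrt(3), 1 - sqrt(3)) / (4 * sqrt(2))

# One level of 1-D approximation along the columns of a matrix
# (i.e. filtering each column), with symmetric boundary extension and a
# 1/sqrt(2) rescale so a constant signal maps to the same constant.
dwt_approx_cols <- function(m) {
  n <- nrow(m)
  if (n %% 2L == 1L) {           # reflect-pad one sample to an even length
    m <- rbind(m, m[n, , drop = FALSE])
    n <- n + 1L
  }
  # symmetric extension by two samples at the tail
  me <- rbind(m, m[n, , drop = FALSE], m[n - 1L, , drop = FALSE])
  idx <- seq(1L, n, by = 2L)
  a <- .db2_lo[1] * me[idx, , drop = FALSE] +
       .db2_lo[2] * me[idx + 1L, , drop = FALSE] +
       .db2_lo[3] * me[idx + 2L, , drop = FALSE] +
       .db2_lo[4] * me[idx + 3L, , drop = FALSE]
  a / sqrt(2)
}

#' Decimate a slide with the Daubechies-2 wavelet
#'
#' Each level keeps the approximation band of a separable Daubechies-2
#' orthogonal wavelet transform per color channel, halving both image
#' dimensions and doubling the pixel size. Approximation coefficients
#' are rescaled so a constant image maps to the same constant; boundaries
#' use symmetric extension. `levels = 3` divides the resolution by 8
#' (e.g. 0.5 to 4 um/px).
#'
#' @param slide A [virtual_slide()].
#' @param levels Number of halving levels (>= 1).
#' @return A [virtual_slide()] with resolution multiplied by `2^levels`.
#' @export
decimate_wavelet <- function(slide, levels) {
  stopifnot(inherits(slide, "virtual_slide"))
  if (!is.numeric(levels) || levels < 1L || levels != round(levels))
    stop("levels must be a positive integer")
  d <- slide_dim(slide)
  if (min(d) < 2^levels)
    stop(sprintf("image too small for %d levels: need >= %d px per side",
                 levels, 2^levels))
  px <- slide$pixels
  for (l in seq_len(levels)) {
    out <- vector("list", 3L)
    for (ch in 1:3) {
      a <- dwt_approx_cols(px[, , ch])
      a <- t(dwt_approx_cols(t(a)))
      out[[ch]] <- a
    }
    px <- array(unlist(out), dim = c(dim(out[[1]]), 3L))
  }
  px[px < 0] <- 0; px[px > 1] <- 1
  virtual_slide(px, slide$resolution * 2^levels)
}
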
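#' Laplacian-of-Gaussian filter
#'
#' Convolves a 3-D volume with the analytic Laplacian-of-Gaussian kernel at
#' scale `sigma` (mm), as the separable sum
#' \eqn{G''(x)G(y)G(z) + G(x)G''(y)G(z) + G(x)G(y)G''(z)}. Taps are the
#' analytic derivatives sampled at voxel centers (anisotropic spacing
#' handled per axis), truncated at 5 sigma; the second-derivative taps are
#' mean-corrected to sum exactly to zero, so a constant volume maps to zero
#' and a linear ramp maps to zero away from the boundary (replicate padding).
#'
#' @param volume 3-D numeric array.
#' @param sigma Gaussian scale in mm, > 0.
#' @param spacing voxel spacing per axis in mm (length 3).
#' @return filtered 3-D array, same dimensions.
#' @export
log_filter <- function(volume, sigma, spacing = c(1, 1, 1)) {
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0)
    stop("sigma must be a positive scalar")
  stopifnot(length(dim(volume)) == 3L, length(spacing) == 3L, all(spacing > 0))
  taps <- lapply(1:3, function(a) {
    r <- ceiling(5 * sigma / spacing[a])
    x <- (-r:r) * spacing[a]
    g <- exp(-x^2 / (2 * sigma^2)) / (sigma * sqrt(2 * pi))
    g2 <- (x^2 - sigma^2) / sigma^4 * g
    g2 <- g2 - mean(g2)                       # exact zero-sum
    list(g = g, g2 = g2)
  })
  sep_conv3 <- function(t1, t2, t3) {
    out <- conv_axis(volume, t1, 1L)
    out <- conv_axis(out, t2, 2L)
    conv_axis(out, t3, 3L)
  }
  sep_conv3(taps[[1]]$g2, taps[[2]]$g, taps[[3]]$g) +
    sep_conv3(taps[[1]]$g, taps[[2]]$g2, taps[[3]]$g) +
    sep_conv3(taps[[1]]$g, taps[[2]]$g, taps[[3]]$g2)
}

# 1-D convolution along one axis with replicate (nearest) padding
conv_axis <- function(a, taps, axis) {
  d <- dim(a)
  r <- (length(taps) - 1L) / 2L
  out <- array(0, d)
  for (m in seq_along(taps)) {
    if (taps[m] == 0) next
    k <- m - 1L - r
    idx <- pmin(pmax(seq_len(d[axis]) + k, 1L), d[axis])
    shifted <- switch(axis,
                      a[idx, , , drop = FALSE],
                      a[, idx, , drop = FALSE],
                      a[, , idx, drop = FALSE])
    out <- out + taps[m] * shifted
  }
  out
}

#' Single-level 3-D wavelet decomposition
#'
#' Decimated single-level separable wavelet transform with orthonormal taps
#' (Haar by default: low = (1,1)/sqrt(2), high = (1,-1)/sqrt(2)), yielding
#' the 8 subbands LLL ... HHH. Subband label letters follow array axis order
#' (first letter = axis 1). With even axis lengths the transform is
#' orthonormal, so total squared-coefficient energy equals input energy
#' (Parseval); odd axes are edge-replicated to even length first.
#'
#' @param volume 3-D numeric array, every axis length >= 2.
#' @param low,high analysis filter taps (orthonormal pair).
#' @return named list of 8 half-size arrays, names from [wavelet_subband_labels()].
#' @export
wavelet_subbands <- function(volume, low = c(1, 1) / sqrt(2),
                             high = c(1, -1) / sqrt(2)) {
  d <- dim(volume)
  if (length(d) != 3L || any(d < 2L)) stop("every axis must have length >= 2")
  out <- list()
  for (lab in wavelet_subband_labels()) {
    a <- volume
    for (ax in 1:3) {
      taps <- if (substr(lab, ax, ax) == "L") low else high
      a <- dwt_axis(a, taps, ax)
    }
    out[[lab]] <- a
  }
  out
}

# decimated filter-downsample along one axis; odd length edge-replicated
dwt_axis <- function(a, taps, axis) {
  d <- dim(a)
  n <- d[axis]
  if (n %% 2L == 1L) {                        # replicate last plane
    idx <- c(seq_len(n), n)
    a <- switch(axis, a[idx, , , drop = FALSE], a[, idx, , drop = FALSE],
                a[, , idx, drop = FALSE])
    n <- n + 1L
  }
  i1 <- seq(1L, n, by = 2L); i2 <- i1 + 1L
  pick <- function(idx) switch(axis, a[idx, , , drop = FALSE],
                               a[, idx, , drop = FALSE], a[, , idx, drop = FALSE])
  taps[1] * pick(i1) + taps[2] * pick(i2)
}

# subband-resolution mask: a block is foreground if any constituent voxel is
downsample_mask <- function(mask) {
  m <- array(as.logical(mask), dim(mask))
  for (ax in 1:3) {
    n <- dim(m)[ax]
    if (n %% 2L == 1L) {
      idx <- c(seq_len(n), n)
      m <- switch(ax, m[idx, , , drop = FALSE], m[, idx, , drop = FALSE],
                  m[, , idx, drop = FALSE])
      n <- n + 1L
    }
    i1 <- seq(1L, n, by = 2L); i2 <- i1 + 1L
    pick <- function(idx) switch(ax, m[idx, , , drop = FALSE],
                                 m[, idx, , drop = FALSE], m[, , idx, drop = FALSE])
    m <- pick(i1) | pick(i2)
  }
  m
}
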
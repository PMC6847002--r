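# Separable convolution machinery.
#
# Convolution along one axis of a 3D array is expressed as a banded-matrix
# multiplication: out[i] = sum_k w_k * in[clamp(i + off_k)], with replicate
# (nearest-edge) padding folded into the band matrix. Axis lengths here are
# small (tens of slices/pixels), so the dense n x n band matrix is cheap and
# the matmul is fast.

.band_matrix <- function(n, weights, offsets) {
  K <- matrix(0, n, n)
  idx <- seq_len(n)
  for (k in seq_along(offsets)) {
    j <- pmin(pmax(idx + offsets[k], 1L), n)
    ij <- cbind(idx, j)
    K[ij] <- K[ij] + weights[k]
  }
  K
}

.conv_axis <- function(a, axis, weights, offsets) {
  d <- dim(a)
  K <- .band_matrix(d[axis], weights, offsets)
  perm <- c(axis, setdiff(seq_len(3), axis))
  m <- matrix(aperm(a, perm), nrow = d[axis])
  out <- array(K %*% m, dim = d[perm])
  aperm(out, order(perm))
}

.gaussian_kernel <- function(sigma) {
  h <- max(1L, ceiling(4 * sigma))
  off <- seq.int(-h, h)
  w <- stats::dnorm(off, sd = sigma)
  list(weights = w / sum(w), offsets = off)
}

.smooth_axis <- function(a, axis, sigma) {
  k <- .gaussian_kernel(sigma)
  .conv_axis(a, axis, k$weights, k$offsets)
}

# discrete second difference along an axis (replicate padding, so a constant
# or an axis-aligned linear ramp maps to ~0 in the interior)
.second_diff_axis <- function(a, axis) {
  .conv_axis(a, axis, c(1, -2, 1), c(-1L, 0L, 1L))
}

#' Rolling-ball background subtraction
#'
#' Estimates, slice by slice, a smooth background as the grayscale opening of
#' the image with a ball-shaped (hemispherical) structuring element of the
#' given radius — the classical rolling-ball construction: the background is
#' the upper envelope of a ball of radius `radius` rolled beneath the
#' intensity surface. Diffraction-limited spots much brighter than the ball
#' height cannot be entered by the ball and are preserved; the smooth
#' background (flat or slowly varying) is removed. The result is
#' `input - background`, clipped at zero.
#'
#' @param stack An [image_stack()] (or a 3D array).
#' @param radius Ball radius in pixels (default 2).
#' @return An `image_stack` of the background-subtracted intensities.
#' @export
rolling_ball_subtract <- function(stack, radius = 2) {
  if (!(is.numeric(radius) && length(radius) == 1 && radius >= 1)) {
    stop("rolling-ball radius must be a single number >= 1")
  }
  s <- as_image_stack(stack)
  v <- s$voxels
  for (z in seq_len(dim(v)[1])) {
    sl <- v[z, , , drop = TRUE]
    bg <- .rolling_ball_background(sl, radius)
    v[z, , ] <- pmax(sl - bg, 0)
  }
  new_image_stack(v, s$z_step, s$pixel_size, s$channel)
}

.rolling_ball_background <- function(m, radius) {
  r <- ceiling(radius)
  off <- expand.grid(dy = -r:r, dx = -r:r)
  d2 <- off$dy^2 + off$dx^2
  keep <- d2 <= radius^2
  off <- off[keep, ]
  b <- sqrt(radius^2 - d2[keep])
  nr <- nrow(m); nc <- ncol(m)
  pad <- function(x) {
    ri <- pmin(pmax(seq.int(1 - r, nr + r), 1L), nr)
    ci <- pmin(pmax(seq.int(1 - r, nc + r), 1L), nc)
    x[ri, ci, drop = FALSE]
  }
  mp <- pad(m)
  ero <- matrix(Inf, nr, nc)
  for (k in seq_len(nrow(off))) {
    sh <- mp[r + off$dy[k] + seq_len(nr), r + off$dx[k] + seq_len(nc)]
    ero <- pmin(ero, sh - b[k])
  }
  ep <- pad(ero)
  dil <- matrix(-Inf, nr, nc)
  for (k in seq_len(nrow(off))) {
    sh <- ep[r + off$dy[k] + seq_len(nr), r + off$dx[k] + seq_len(nc)]
    dil <- pmax(dil, sh + b[k])
  }
  dil
}

#' Anisotropic 3D Laplacian-of-Gaussian filter
#'
#' Smooths the stack with an anisotropic Gaussian (lateral sigma in pixels,
#' axial sigma in slices, accommodating z-steps different from the pixel
#' size) and returns the negated discrete Laplacian of the result, so that
#' blob centers appear as response maxima. Stacks with fewer than 3 slices
#' fall back to an independent 2D LoG per slice, with a warning.
#'
#' @param stack An [image_stack()] (or a 3D array).
#' @param sigma_lateral Gaussian sigma in the row/col directions, pixels.
#' @param sigma_axial Gaussian sigma in the slice direction, slices.
#' @return An `image_stack` holding the (signed) filter response.
#' @export
log_filter_3d <- function(stack, sigma_lateral = 2, sigma_axial = 1) {
  stopifnot(sigma_lateral > 0, sigma_axial > 0)
  s <- as_image_stack(stack)
  v <- s$voxels
  use_z <- dim(v)[1] >= 3
  if (!use_z) {
    warning("stack has < 3 slices; applying 2D Laplacian of Gaussian per slice")
  }
  sm <- v
  if (use_z) sm <- .smooth_axis(sm, 1L, sigma_axial)
  sm <- .smooth_axis(sm, 2L, sigma_lateral)
  sm <- .smooth_axis(sm, 3L, sigma_lateral)
  resp <- .second_diff_axis(sm, 2L) + .second_diff_axis(sm, 3L)
  if (use_z) resp <- resp + .second_diff_axis(sm, 1L)
  new_image_stack(-resp, s$z_step, s$pixel_size, s$channel)
}

# 2D LoG used by the movie peak detector; same construction restricted to a
# single plane.
.log_filter_2d <- function(m, sigma) {
  a <- array(m, dim = c(1L, nrow(m), ncol(m)))
  sm <- .smooth_axis(.smooth_axis(a, 2L, sigma), 3L, sigma)
  resp <- .second_diff_axis(sm, 2L) + .second_diff_axis(sm, 3L)
  -resp[1, , , drop = TRUE]
}
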
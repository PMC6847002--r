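#' Per-slice 2D local maxima of a filtered stack
#'
#' Finds, independently in every z-slice, all pixels that (a) lie inside the
#' nucleus ROI, (b) exceed `threshold`, (c) are greater than or equal to all
#' 8 in-slice neighbors and strictly greater than at least one of them
#' (an equal-intensity plateau contributes a single representative: the first
#' pixel in row-major scan order), (d) are not on the slice border (edge
#' maxima excluded), and (e) when `noise_tolerance > 0`, exceed their largest
#' neighbor by more than `noise_tolerance`.
#'
#' @param filtered An [image_stack()] of filter responses (typically from
#'   [log_filter_3d()]).
#' @param roi Optional [nucleus_roi()] or logical matrix with the stack's
#'   row/col shape; `NULL` means the whole field of view.
#' @param threshold Intensity threshold; maxima must strictly exceed it.
#' @param noise_tolerance Non-negative tolerance (default 0, the setting used
#'   throughout the locus pipeline).
#' @return A data frame with columns `slice`, `row`, `col`, `intensity`
#'   (1-based indices), ordered by (slice, row, col).
#' @export
find_slice_maxima <- function(filtered, roi = NULL, threshold,
                              noise_tolerance = 0) {
  stopifnot(is.numeric(threshold), length(threshold) == 1, is.finite(threshold),
            noise_tolerance >= 0)
  s <- as_image_stack(filtered)
  v <- s$voxels
  mask <- .roi_mask(roi, dim(v)[2], dim(v)[3])
  out <- vector("list", dim(v)[1])
  for (z in seq_len(dim(v)[1])) {
    m <- .local_maxima_2d(v[z, , , drop = TRUE], threshold, noise_tolerance,
                          mask)
    if (nrow(m)) m$slice <- z
    out[[z]] <- m
  }
  res <- do.call(rbind, out[vapply(out, nrow, 0L) > 0])
  if (is.null(res)) {
    res <- data.frame(slice = integer(), row = integer(), col = integer(),
                      intensity = numeric())
  }
  rownames(res) <- NULL
  res[, c("slice", "row", "col", "intensity")]
}

.roi_mask <- function(roi, nr, nc) {
  if (is.null(roi)) return(matrix(TRUE, nr, nc))
  m <- if (inherits(roi, "nucleus_roi")) roi$mask else roi
  if (!is.matrix(m) || nrow(m) != nr || ncol(m) != nc) {
    stop(sprintf("ROI mask must be a %d x %d matrix matching the stack", nr, nc))
  }
  matrix(as.logical(m), nr, nc)
}

.local_maxima_2d <- function(m, threshold, noise_tolerance, mask = NULL) {
  nr <- nrow(m); nc <- ncol(m)
  empty <- data.frame(row = integer(), col = integer(), intensity = numeric())
  if (nr < 3 || nc < 3) return(empty)
  ri <- 2:(nr - 1); ci <- 2:(nc - 1)
  center <- m[ri, ci, drop = FALSE]
  nmax <- matrix(-Inf, length(ri), length(ci))
  nmin <- matrix(Inf, length(ri), length(ci))
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    nb <- m[ri + dy, ci + dx, drop = FALSE]
    nmax <- pmax(nmax, nb)
    nmin <- pmin(nmin, nb)
  }
  cand <- center >= nmax & center > nmin & center > threshold
  if (noise_tolerance > 0) cand <- cand & (center - nmax > noise_tolerance)
  if (!is.null(mask)) cand <- cand & mask[ri, ci, drop = FALSE]
  if (!any(cand)) return(empty)
  w <- which(cand, arr.ind = TRUE)
  row <- w[, 1] + 1L; col <- w[, 2] + 1L
  val <- m[cbind(row, col)]
  # row-major scan order: rows outer, columns inner
  o <- order(row, col)
  row <- row[o]; col <- col[o]; val <- val[o]
  # plateau suppression: drop a candidate 8-adjacent to any earlier candidate
  # of equal intensity (transitively keeps one representative per plateau)
  keep <- rep(TRUE, length(row))
  if (length(row) > 1) {
    for (i in 2:length(row)) {
      j <- seq_len(i - 1)
      adj <- abs(row[j] - row[i]) <= 1 & abs(col[j] - col[i]) <= 1 &
        val[j] == val[i]
      if (any(adj)) keep[i] <- FALSE
    }
  }
  data.frame(row = row[keep], col = col[keep], intensity = val[keep])
}

#' Promote per-slice maxima to 3D loci via the cube test
#'
#' A 2D maximum is accepted as a 3D locus if and only if its intensity is
#' greater than or equal to every voxel of a `(2h+1)^3` cube centered on it
#' (default `h = 2`, a 5x5x5 cube), the cube being truncated at the stack
#' boundaries. The comparison is non-strict so a maximum never disqualifies
#' itself; when two candidates of exactly equal intensity lie within each
#' other's cubes, only the first in (slice, row, col) scan order is kept.
#'
#' @param maxima Data frame from [find_slice_maxima()].
#' @param filtered The same filtered [image_stack()] the maxima came from.
#' @param cube_halfwidth Cube half-width `h >= 1` in voxels (default 2).
#' @return A data frame with columns `z`, `y`, `x`, `intensity` (1-based
#'   voxel indices).
#' @export
select_3d_maxima <- function(maxima, filtered, cube_halfwidth = 2) {
  stopifnot(cube_halfwidth >= 1)
  h <- as.integer(cube_halfwidth)
  s <- as_image_stack(filtered)
  v <- s$voxels
  d <- dim(v)
  empty <- data.frame(z = integer(), y = integer(), x = integer(),
                      intensity = numeric())
  if (!nrow(maxima)) return(empty)
  o <- order(maxima$slice, maxima$row, maxima$col)
  maxima <- maxima[o, ]
  pass <- logical(nrow(maxima))
  for (i in seq_len(nrow(maxima))) {
    z <- maxima$slice[i]; y <- maxima$row[i]; x <- maxima$col[i]
    cube <- v[max(1, z - h):min(d[1], z + h),
              max(1, y - h):min(d[2], y + h),
              max(1, x - h):min(d[3], x + h)]
    pass[i] <- maxima$intensity[i] >= max(cube)
  }
  cand <- maxima[pass, , drop = FALSE]
  if (!nrow(cand)) return(empty)
  keep <- rep(TRUE, nrow(cand))
  for (i in seq_len(nrow(cand))[-1]) {
    j <- which(keep[seq_len(i - 1)])
    tie <- cand$intensity[j] == cand$intensity[i] &
      abs(cand$slice[j] - cand$slice[i]) <= h &
      abs(cand$row[j] - cand$row[i]) <= h &
      abs(cand$col[j] - cand$col[i]) <= h
    if (any(tie)) keep[i] <- FALSE
  }
  cand <- cand[keep, , drop = FALSE]
  res <- data.frame(z = cand$slice, y = cand$row, x = cand$col,
                    intensity = cand$intensity)
  rownames(res) <- NULL
  res
}

#' Call genomic loci in a z-stack
#'
#' Runs the full four-stage locus-calling procedure: rolling-ball background
#' subtraction, anisotropic 3D Laplacian-of-Gaussian filtering, per-slice
#' local maxima above a threshold inside the nucleus ROI, and the 5x5x5-voxel
#' 3D-maximum cube test. When `threshold = NULL` a reproducible data-driven
#' stand-in for a manually chosen threshold is used:
#' `median + threshold_k * MAD` of the filtered voxels inside the ROI.
#'
#' @inheritParams rolling_ball_subtract
#' @inheritParams log_filter_3d
#' @inheritParams find_slice_maxima
#' @inheritParams select_3d_maxima
#' @param rolling_ball_radius Radius for [rolling_ball_subtract()] (default 2).
#' @param threshold Intensity threshold on the filtered stack, or `NULL` for
#'   the median + `threshold_k` * MAD rule.
#' @param threshold_k Multiplier for the MAD-based threshold (default 6).
#' @return A data frame of loci (`z`, `y`, `x`, `intensity`, and `nucleus_id`
#'   when `roi` carries one), with the threshold used stored in
#'   `attr(, "threshold")`.
#' @export
detect_loci <- function(stack, roi = NULL,
                        rolling_ball_radius = 2,
                        sigma_lateral = 2, sigma_axial = 1,
                        threshold = NULL, threshold_k = 6,
                        noise_tolerance = 0, cube_halfwidth = 2) {
  s <- as_image_stack(stack)
  filt <- log_filter_3d(rolling_ball_subtract(s, rolling_ball_radius),
                        sigma_lateral, sigma_axial)
  mask <- .roi_mask(roi, dim(filt$voxels)[2], dim(filt$voxels)[3])
  if (is.null(threshold)) {
    inroi <- filt$voxels[rep(mask, each = dim(filt$voxels)[1])]
    threshold <- stats::median(inroi) + threshold_k * stats::mad(inroi)
    # floor keeps float residue of featureless stacks below threshold
    threshold <- max(threshold, 1e-8 * max(abs(s$voxels)))
  }
  mx <- find_slice_maxima(filt, roi = mask, threshold = threshold,
                          noise_tolerance = noise_tolerance)
  loci <- select_3d_maxima(mx, filt, cube_halfwidth = cube_halfwidth)
  if (inherits(roi, "nucleus_roi") && nrow(loci)) {
    loci$nucleus_id <- roi$nucleus_id
  }
  attr(loci, "threshold") <- threshold
  loci
}

#' Count loci per nucleus
#'
#' Assigns each locus to the nucleus whose mask contains its (row, col)
#' projection and tabulates per-nucleus counts. Nuclei with no loci appear
#' with a count of 0; a locus falling outside every ROI is an error.
#'
#' @param loci Data frame of loci with columns `y`, `x` (from
#'   [select_3d_maxima()] or [detect_loci()]).
#' @param rois A list of [nucleus_roi()] objects, or a labeled integer mask
#'   matrix (0 = background).
#' @return Data frame with columns `nucleus_id`, `n_loci`.
#' @export
count_loci <- function(loci, rois) {
  if (is.matrix(rois)) rois <- split_labeled_mask(rois)
  stopifnot(length(rois) >= 1,
            all(vapply(rois, inherits, TRUE, "nucleus_roi")))
  ids <- vapply(rois, function(r) r$nucleus_id, 1L)
  n <- integer(length(rois))
  assigned <- rep(FALSE, nrow(loci))
  for (k in seq_along(rois)) {
    if (nrow(loci)) {
      inside <- rois[[k]]$mask[cbind(loci$y, loci$x)]
      n[k] <- sum(inside & !assigned)
      assigned <- assigned | inside
    }
  }
  if (any(!assigned)) {
    bad <- which(!assigned)
    stop(sprintf("locus outside all ROIs (e.g. z=%d y=%d x=%d)",
                 loci$z[bad[1]], loci$y[bad[1]], loci$x[bad[1]]))
  }
  data.frame(nucleus_id = ids, n_loci = n)
}
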
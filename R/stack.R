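#' Fluorescence image containers
#'
#' An `image_stack` is a single-channel 3D fluorescence z-stack: a numeric
#' array indexed `[slice, row, col]` (1-based, the R convention) together with
#' its voxel dimensions. A `time_lapse` is a single-channel 2D movie: an array
#' indexed `[frame, row, col]` with its frame interval and pixel size.
#'
#' @param voxels Numeric 3D array `[slice, row, col]` of non-negative, finite
#'   intensities.
#' @param z_step Axial voxel spacing, micrometres per slice.
#' @param pixel_size Lateral pixel size, micrometres per pixel.
#' @param channel Optional channel label (e.g. `"FRET"`, `"EGFP"`).
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(voxels, z_step = 0.25, pixel_size = 0.16, channel = "") {
  stopifnot(is.array(voxels), length(dim(voxels)) == 3, all(dim(voxels) >= 1))
  if (!all(is.finite(voxels)) || any(voxels < 0)) {
    stop("image_stack intensities must be finite and >= 0")
  }
  new_image_stack(voxels, z_step, pixel_size, channel)
}

# internal constructor without the non-negativity check (filter responses may
# legitimately be negative)
new_image_stack <- function(voxels, z_step, pixel_size, channel = "") {
  stopifnot(z_step > 0, pixel_size > 0)
  structure(
    list(voxels = voxels, z_step = z_step, pixel_size = pixel_size,
         channel = as.character(channel)),
    class = "image_stack"
  )
}

as_image_stack <- function(x, z_step = 0.25, pixel_size = 0.16, channel = "") {
  if (inherits(x, "image_stack")) return(x)
  image_stack(x, z_step = z_step, pixel_size = pixel_size, channel = channel)
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf(
    "image_stack: %d slices x %d rows x %d cols (%g um/px, %g um/slice)%s\n",
    d[1], d[2], d[3], x$pixel_size, x$z_step,
    if (nzchar(x$channel)) paste0(" [", x$channel, "]") else ""))
  invisible(x)
}

#' @rdname image_stack
#' @param frames Numeric 3D array `[frame, row, col]`.
#' @param frame_interval Seconds per frame.
#' @export
time_lapse <- function(frames, frame_interval = 0.1, pixel_size = 0.16,
                       channel = "") {
  stopifnot(is.array(frames), length(dim(frames)) == 3, dim(frames)[1] >= 2,
            frame_interval > 0, pixel_size > 0)
  if (!all(is.finite(frames)) || any(frames < 0)) {
    stop("time_lapse intensities must be finite and >= 0")
  }
  structure(
    list(frames = frames, frame_interval = frame_interval,
         pixel_size = pixel_size, channel = as.character(channel)),
    class = "time_lapse"
  )
}

#' @export
print.time_lapse <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "time_lapse: %d frames x %d rows x %d cols (%g um/px, %g s/frame)\n",
    d[1], d[2], d[3], x$pixel_size, x$frame_interval))
  invisible(x)
}

#' Nucleus region of interest
#'
#' A binary 2D mask (rows x cols) applied identically to every slice of a
#' z-stack, with an integer nucleus identifier.
#'
#' @param mask Logical (or 0/1) matrix with at least one foreground pixel.
#' @param nucleus_id Integer identifier.
#' @return An object of class `nucleus_roi`.
#' @export
nucleus_roi <- function(mask, nucleus_id = 1L) {
  mask <- matrix(as.logical(mask), nrow = nrow(mask), ncol = ncol(mask))
  if (!any(mask)) stop("nucleus_roi mask has no foreground pixels")
  structure(list(mask = mask, nucleus_id = as.integer(nucleus_id)),
            class = "nucleus_roi")
}

#' Split a labeled mask into per-nucleus ROIs
#'
#' @param labels Integer matrix; 0 = background, each positive label one
#'   nucleus.
#' @return List of [nucleus_roi()] objects, one per positive label.
#' @export
split_labeled_mask <- function(labels) {
  stopifnot(is.matrix(labels))
  ids <- sort(unique(labels[labels > 0]))
  lapply(ids, function(i) nucleus_roi(labels == i, nucleus_id = i))
}
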
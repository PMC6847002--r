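#' Read and write multi-page grayscale TIFF stacks
#'
#' Stacks and movies are stored as multi-page grayscale TIFFs, 16 bits per
#' sample, one page per slice/frame. Intensities are scaled by
#' `2^16 - 1` on write and restored on read, so integer camera counts up to
#' 65535 round-trip exactly. RGB pages or pages of inconsistent shape are a
#' format error.
#'
#' @param stack An [image_stack()].
#' @param path TIFF file path.
#' @return `write_stack` invisibly returns `path`; `read_stack` returns an
#'   [image_stack()].
#' @export
write_stack <- function(stack, path) {
  s <- as_image_stack(stack)
  pages <- lapply(seq_len(dim(s$voxels)[1]), function(z) {
    s$voxels[z, , , drop = TRUE] / 65535
  })
  if (any(vapply(pages, max, 1) > 1)) stop("intensities exceed 16-bit range")
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_stack
#' @param z_step,pixel_size Voxel dimensions in um, supplied from the
#'   configuration (they override any TIFF resolution metadata).
#' @param channel Optional channel label.
#' @export
read_stack <- function(path, z_step = 0.25, pixel_size = 0.16, channel = "") {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (any(!vapply(pages, is.matrix, TRUE))) {
    stop("format error: TIFF pages must be single-channel grayscale")
  }
  d1 <- dim(pages[[1]])
  if (any(vapply(pages, function(p) !identical(dim(p), d1), TRUE))) {
    stop("format error: TIFF pages have inconsistent shapes")
  }
  vox <- array(0, dim = c(length(pages), d1[1], d1[2]))
  for (z in seq_along(pages)) vox[z, , ] <- round(pages[[z]] * 65535)
  image_stack(vox, z_step = z_step, pixel_size = pixel_size, channel = channel)
}

#' @rdname write_stack
#' @param movie A [time_lapse()].
#' @export
write_movie <- function(movie, path) {
  stopifnot(inherits(movie, "time_lapse"))
  write_stack(new_image_stack(movie$frames, 1, movie$pixel_size), path)
}

#' @rdname write_stack
#' @param frame_interval Seconds per frame for the movie being read.
#' @export
read_movie <- function(path, frame_interval = 0.1, pixel_size = 0.16,
                       channel = "") {
  s <- read_stack(path, z_step = 1, pixel_size = pixel_size, channel = channel)
  time_lapse(s$voxels, frame_interval = frame_interval,
             pixel_size = pixel_size, channel = channel)
}

#' Ground-truth sidecar files
#'
#' A synthetic scene or movie truth is stored as a CSV of coordinates plus a
#' JSON header with the generator parameters and seed, so a rendered TIFF can
#' be re-analyzed against its exact truth.
#'
#' @param truth A `scene_truth` or `movie_truth` object.
#' @param base Base path; `<base>.csv` and `<base>.json` are written.
#' @return `write_truth` invisibly returns `base`; `read_truth` restores the
#'   object.
#' @export
write_truth <- function(truth, base) {
  if (inherits(truth, "scene_truth")) {
    utils::write.csv(truth$positions, paste0(base, ".csv"), row.names = FALSE)
    header <- list(kind = "scene", seed = truth$seed,
                   mask_dim = dim(truth$nucleus_mask),
                   mask_fg = which(truth$nucleus_mask))
  } else if (inherits(truth, "movie_truth")) {
    utils::write.csv(truth$tracks, paste0(base, ".csv"), row.names = FALSE)
    header <- list(kind = "movie", seed = truth$seed, D = truth$D,
                   v = truth$v, loc_noise_sd = truth$loc_noise_sd,
                   frame_interval = truth$frame_interval,
                   extent = truth$extent)
  } else stop("unknown truth object")
  jsonlite::write_json(header, paste0(base, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(base)
}

#' @rdname write_truth
#' @export
read_truth <- function(base) {
  header <- jsonlite::read_json(paste0(base, ".json"), simplifyVector = TRUE)
  tab <- utils::read.csv(paste0(base, ".csv"))
  if (identical(header$kind, "scene")) {
    mask <- matrix(FALSE, header$mask_dim[1], header$mask_dim[2])
    mask[header$mask_fg] <- TRUE
    structure(list(positions = tab, nucleus_mask = mask,
                   seed = as.integer(header$seed)), class = "scene_truth")
  } else if (identical(header$kind, "movie")) {
    structure(list(tracks = tab, D = header$D, v = header$v,
                   loc_noise_sd = header$loc_noise_sd,
                   frame_interval = header$frame_interval,
                   extent = header$extent, seed = as.integer(header$seed)),
              class = "movie_truth")
  } else stop("unknown truth sidecar kind")
}
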
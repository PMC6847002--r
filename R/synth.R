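#' Synthetic nucleus mask
#'
#' An elliptical binary nucleus mask centered in a `rows x cols` field with
#' semi-axes a fixed fraction of the field, emulating the interphase nucleus
#' outline inside which loci are placed.
#'
#' @param rows,cols Field dimensions in pixels.
#' @param fill Fraction of the half-dimension used as ellipse semi-axis
#'   (default 0.72, leaving a border so no locus sits at the image edge).
#' @return Logical matrix.
#' @export
make_nucleus_mask <- function(rows, cols, fill = 0.72) {
  cy <- (rows + 1) / 2; cx <- (cols + 1) / 2
  a <- fill * (rows - 1) / 2; b <- fill * (cols - 1) / 2
  outer(seq_len(rows), seq_len(cols),
        function(y, x) ((y - cy) / a)^2 + ((x - cx) / b)^2 <= 1)
}

# 4-neighbor binary erosion, used to keep spot centers away from the mask rim
.erode_mask <- function(mask, k) {
  m <- mask
  for (i in seq_len(k)) {
    nr <- nrow(m); nc <- ncol(m)
    up <- rbind(m[-1, , drop = FALSE], FALSE)
    dn <- rbind(FALSE, m[-nr, , drop = FALSE])
    lf <- cbind(m[, -1, drop = FALSE], FALSE)
    rt <- cbind(FALSE, m[, -nc, drop = FALSE])
    m <- m & up & dn & lf & rt
  }
  m
}

# rejection-sample continuous spot centers inside an eroded mask with a
# minimum pairwise 3D separation; z kept >= 2 slices from the stack faces
.place_spots <- function(n, mask, nz, min_separation, margin,
                         existing = NULL, min_dist_existing = 0,
                         max_tries = 400) {
  placed <- matrix(numeric(0), ncol = 3)
  if (n == 0) return(placed)
  core <- .erode_mask(mask, margin)
  fg <- which(core, arr.ind = TRUE)
  if (nrow(fg) == 0) stop("placement error: nucleus mask too small for margin")
  zlo <- min(3, (nz + 1) / 2); zhi <- max(nz - 2, (nz + 1) / 2)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (t in seq_len(max_tries)) {
      px <- fg[sample.int(nrow(fg), 1), ]
      pos <- c(stats::runif(1, zlo, zhi),
               px[1] + stats::runif(1, -0.5, 0.5),
               px[2] + stats::runif(1, -0.5, 0.5))
      all_pts <- rbind(placed, existing)
      sep_ok <- TRUE
      if (!is.null(all_pts) && nrow(all_pts)) {
        d <- sqrt(rowSums(sweep(all_pts, 2, pos)^2))
        lim <- c(rep(min_separation, nrow(placed)),
                 rep(max(min_dist_existing, min_separation),
                     nrow(all_pts) - nrow(placed)))
        sep_ok <- all(d >= lim)
      }
      if (sep_ok) { placed <- rbind(placed, pos); ok <- TRUE; break }
    }
    if (!ok) stop("placement error: cannot place spots at the requested separation")
  }
  rownames(placed) <- NULL
  placed
}

# render anisotropic 3D Gaussian spots (amplitude = peak photons) into a
# zero array; each spot only evaluated within +/- 5 sigma
.render_spots_3d <- function(shape, positions, amplitudes, sigma_l, sigma_a) {
  a <- array(0, dim = shape)
  if (is.null(positions) || nrow(positions) == 0) return(a)
  hz <- ceiling(5 * sigma_a); hl <- ceiling(5 * sigma_l)
  for (i in seq_len(nrow(positions))) {
    z0 <- positions[i, 1]; y0 <- positions[i, 2]; x0 <- positions[i, 3]
    zi <- max(1, floor(z0 - hz)):min(shape[1], ceiling(z0 + hz))
    yi <- max(1, floor(y0 - hl)):min(shape[2], ceiling(y0 + hl))
    xi <- max(1, floor(x0 - hl)):min(shape[3], ceiling(x0 + hl))
    gz <- exp(-(zi - z0)^2 / (2 * sigma_a^2))
    gy <- exp(-(yi - y0)^2 / (2 * sigma_l^2))
    gx <- exp(-(xi - x0)^2 / (2 * sigma_l^2))
    # c() keeps the addition shape-agnostic when an index range has length 1
    a[zi, yi, xi] <- a[zi, yi, xi] + c(amplitudes[i] * (gz %o% gy %o% gx))
  }
  a
}

# Poisson shot noise + Gaussian read noise + quantization
.apply_camera <- function(expected, read_noise_sd, bit_depth,
                          shot_noise = TRUE) {
  d <- dim(expected)
  x <- if (shot_noise) stats::rpois(length(expected), lambda = expected)
       else as.numeric(expected)
  if (read_noise_sd > 0) x <- x + stats::rnorm(length(x), 0, read_noise_sd)
  array(round(pmin(pmax(x, 0), 2^bit_depth - 1)), dim = d)
}

#' Generate a synthetic z-stack with known ground truth
#'
#' Renders `n_spots` diffraction-limited spots (anisotropic 3D Gaussians with
#' the PSF sigmas of `params`) at random continuous positions inside an
#' elliptical nucleus mask, over a uniform autofluorescent background, then
#' applies Poisson shot noise, additive Gaussian read noise and quantization.
#' The exact continuous positions and amplitudes are returned as ground
#' truth.
#'
#' @param params An [acquisition_params()] object; `image_shape` is
#'   `c(slices, rows, cols)`.
#' @param n_spots Number of spots (>= 0).
#' @param amplitude_range Length-2 interval of peak amplitudes in photons;
#'   each spot's amplitude is drawn uniformly from it.
#' @param seed Integer seed (mandatory; generation is fully deterministic
#'   given seed and parameters).
#' @param nucleus_mask Optional logical matrix; default an ellipse from
#'   [make_nucleus_mask()].
#' @param min_separation Minimum pairwise 3D spot separation in voxels
#'   (default 6, about 1 um laterally at the default pixel size: distinct
#'   genomic loci resolvable by widefield microscopy); values below
#'   `2 * psf_sigma_lateral` are rejected as unresolvable overlap.
#' @param shot_noise Logical; `FALSE` disables Poisson sampling (useful with
#'   `read_noise_sd = 0` for noiseless renderings).
#' @return A list with `stack` (an [image_stack()]) and `truth` (a
#'   `scene_truth`: data frame `positions` with continuous `z`, `y`, `x`,
#'   `amplitude`; the `nucleus_mask`; the `seed`).
#' @export
generate_stack <- function(params, n_spots, amplitude_range = c(150, 300),
                           seed, nucleus_mask = NULL,
                           min_separation = 6,
                           shot_noise = TRUE) {
  stopifnot(inherits(params, "acquisition_params"), n_spots >= 0,
            !missing(seed), length(amplitude_range) == 2)
  if (min_separation < 2 * params$psf_sigma_lateral) {
    stop("placement error: min_separation below 2 * psf_sigma_lateral is unresolvable overlap")
  }
  shape <- params$image_shape
  if (is.null(nucleus_mask)) nucleus_mask <- make_nucleus_mask(shape[2], shape[3])
  withr::with_seed(as.integer(seed), {
    pos <- .place_spots(n_spots, nucleus_mask, shape[1], min_separation,
                        margin = 3)
    amp <- if (n_spots > 0) stats::runif(n_spots, amplitude_range[1],
                                         amplitude_range[2]) else numeric(0)
    expected <- params$background_level +
      .render_spots_3d(shape, pos, amp, params$psf_sigma_lateral,
                       params$psf_sigma_axial)
    vox <- .apply_camera(expected, params$read_noise_sd, params$bit_depth,
                         shot_noise)
  })
  truth <- structure(
    list(positions = data.frame(z = pos[, 1], y = pos[, 2], x = pos[, 3],
                                amplitude = amp),
         nucleus_mask = nucleus_mask, seed = as.integer(seed)),
    class = "scene_truth")
  list(stack = new_image_stack(vox, params$z_step, params$pixel_size),
       truth = truth)
}

#' Generate a two-channel scene with a controlled colocalized fraction
#'
#' Channel A is generated as in [generate_stack()]. In channel B,
#' `round(coloc_fraction * n_spots)` spots are placed at channel-A positions
#' shifted by `offset_voxels`; the remaining B spots are placed uniformly at
#' random at least 8 voxels (Euclidean) from every channel-A spot, so that by
#' construction they cannot satisfy the default 7x7x7 colocalization cube.
#'
#' @inheritParams generate_stack
#' @param coloc_fraction Proportion in `[0, 1]` of channel-B spots
#'   colocalized with channel A.
#' @param offset_voxels Numeric `c(dz, dy, dx)` applied to colocalized
#'   channel-B spots, in voxels.
#' @return A list with `stack_a`, `stack_b` ([image_stack()]s) and `truth_a`,
#'   `truth_b` (`scene_truth`s; `truth_b$positions$coloc` flags the
#'   constructed colocalized spots).
#' @export
generate_two_channel_scene <- function(params, n_spots, coloc_fraction,
                                       offset_voxels = c(0, 0, 0),
                                       seed, amplitude_range = c(150, 300),
                                       nucleus_mask = NULL,
                                       min_separation = 6,
                                       shot_noise = TRUE) {
  stopifnot(coloc_fraction >= 0, coloc_fraction <= 1,
            length(offset_voxels) == 3, !missing(seed))
  shape <- params$image_shape
  if (is.null(nucleus_mask)) nucleus_mask <- make_nucleus_mask(shape[2], shape[3])
  n_col <- round(coloc_fraction * n_spots)
  withr::with_seed(as.integer(seed), {
    pos_a <- .place_spots(n_spots, nucleus_mask, shape[1], min_separation,
                          margin = 3)
    amp_a <- stats::runif(max(n_spots, 0), amplitude_range[1], amplitude_range[2])
    pos_b_col <- if (n_col > 0) {
      sweep(pos_a[seq_len(n_col), , drop = FALSE], 2, -as.numeric(offset_voxels))
    } else matrix(numeric(0), ncol = 3)
    pos_b_free <- .place_spots(n_spots - n_col, nucleus_mask, shape[1],
                               min_separation, margin = 3,
                               existing = rbind(pos_a, pos_b_col),
                               min_dist_existing = 8)
    pos_b <- rbind(pos_b_col, pos_b_free)
    amp_b <- stats::runif(max(n_spots, 0), amplitude_range[1], amplitude_range[2])
    exp_a <- params$background_level +
      .render_spots_3d(shape, pos_a, amp_a, params$psf_sigma_lateral,
                       params$psf_sigma_axial)
    exp_b <- params$background_level +
      .render_spots_3d(shape, pos_b, amp_b, params$psf_sigma_lateral,
                       params$psf_sigma_axial)
    vox_a <- .apply_camera(exp_a, params$read_noise_sd, params$bit_depth,
                           shot_noise)
    vox_b <- .apply_camera(exp_b, params$read_noise_sd, params$bit_depth,
                           shot_noise)
  })
  mk_truth <- function(pos, amp, coloc = NULL) {
    df <- data.frame(z = pos[, 1], y = pos[, 2], x = pos[, 3],
                     amplitude = amp[seq_len(nrow(pos))])
    if (!is.null(coloc)) df$coloc <- coloc
    structure(list(positions = df, nucleus_mask = nucleus_mask,
                   seed = as.integer(seed)), class = "scene_truth")
  }
  list(
    stack_a = new_image_stack(vox_a, params$z_step, params$pixel_size, "EGFP"),
    stack_b = new_image_stack(vox_b, params$z_step, params$pixel_size, "FRET"),
    truth_a = mk_truth(pos_a, amp_a),
    truth_b = mk_truth(pos_b, amp_b,
                       coloc = seq_len(nrow(pos_b)) <= n_col)
  )
}

#' Simulate 2D locus trajectories
#'
#' Each particle performs, per frame interval `dt`,
#' `x(t + dt) = x(t) + v * dt * u + N(0, 2 D dt)` per axis, where `u` is a
#' unit drift direction fixed per particle (random heading) and the Gaussian
#' step has per-axis variance `2 D dt` (so the 2D Brownian law is
#' `MSD = 4 D dt`). Reported ("observed") positions add independent Gaussian
#' localization noise of standard deviation `loc_noise_sd` per axis.
#'
#' @param n_particles Number of particles.
#' @param n_frames Number of frames (>= 2).
#' @param frame_interval Seconds per frame.
#' @param D Diffusion coefficient, um^2/s (>= 0).
#' @param v Drift speed, um/s (>= 0; 0 for pure diffusion).
#' @param loc_noise_sd Localization noise sd, um.
#' @param seed Integer seed (mandatory).
#' @param extent Numeric `c(width, height)` of the field in um; starting
#'   positions are drawn uniformly with a 1.5 um margin.
#' @return A `movie_truth` object: list with `tracks` (data frame `particle`,
#'   `frame`, `t`, true `x`, `y` and observed `x_obs`, `y_obs`, all in um),
#'   `D`, `v`, `loc_noise_sd`, `frame_interval`, `extent`, `seed`.
#' @export
simulate_tracks <- function(n_particles, n_frames, frame_interval, D, v = 0,
                            loc_noise_sd = 0, seed, extent = c(10, 10)) {
  stopifnot(n_particles >= 1, n_frames >= 2, D >= 0, v >= 0,
            loc_noise_sd >= 0, frame_interval > 0, !missing(seed))
  dt <- frame_interval
  step_sd <- sqrt(2 * D * dt)
  withr::with_seed(as.integer(seed), {
    out <- vector("list", n_particles)
    for (p in seq_len(n_particles)) {
      theta <- stats::runif(1, 0, 2 * pi)
      drift <- v * dt * c(cos(theta), sin(theta))
      x0 <- stats::runif(1, 1.5, extent[1] - 1.5)
      y0 <- stats::runif(1, 1.5, extent[2] - 1.5)
      dx <- c(0, stats::rnorm(n_frames - 1, drift[1], step_sd))
      dy <- c(0, stats::rnorm(n_frames - 1, drift[2], step_sd))
      x <- x0 + cumsum(dx)
      y <- y0 + cumsum(dy)
      out[[p]] <- data.frame(
        particle = p, frame = seq_len(n_frames),
        t = (seq_len(n_frames) - 1) * dt,
        x = x, y = y,
        x_obs = x + stats::rnorm(n_frames, 0, loc_noise_sd),
        y_obs = y + stats::rnorm(n_frames, 0, loc_noise_sd))
    }
  })
  structure(
    list(tracks = do.call(rbind, out), D = D, v = v,
         loc_noise_sd = loc_noise_sd, frame_interval = dt,
         extent = extent, seed = as.integer(seed)),
    class = "movie_truth")
}

#' Convert simulated truth to the track-table format
#'
#' Returns the observed (localization-noise-corrupted) trajectories of a
#' [simulate_tracks()] result as the `track_id`/`frame`/`x`/`y` data frame
#' the dynamics functions consume, bypassing rendering and detection.
#'
#' @param truth A `movie_truth` object.
#' @return Data frame with columns `track_id`, `frame`, `x`, `y` (um).
#' @export
truth_to_tracks <- function(truth) {
  stopifnot(inherits(truth, "movie_truth"))
  data.frame(track_id = truth$tracks$particle, frame = truth$tracks$frame,
             x = truth$tracks$x_obs, y = truth$tracks$y_obs)
}

#' Render a simulated movie
#'
#' Renders each frame as 2D Gaussian spots (lateral PSF sigma of `params`) at
#' the observed truth positions, over the uniform background, with the same
#' Poisson/read-noise camera model as [generate_stack()].
#'
#' @param truth A `movie_truth` from [simulate_tracks()].
#' @param params An [acquisition_params()]; `image_shape` is
#'   `c(frames, rows, cols)` and must cover the truth positions.
#' @param seed Integer seed for the camera noise.
#' @param amplitude Peak spot amplitude in photons (scalar or one per
#'   particle).
#' @inheritParams generate_stack
#' @return A [time_lapse()] object.
#' @export
render_movie <- function(truth, params, seed, amplitude = 200,
                         shot_noise = TRUE) {
  stopifnot(inherits(truth, "movie_truth"),
            inherits(params, "acquisition_params"), !missing(seed))
  tr <- truth$tracks
  shape <- params$image_shape
  n_frames <- max(tr$frame)
  px <- params$pixel_size
  col <- tr$x_obs / px + 1
  row <- tr$y_obs / px + 1
  bad <- row < 1 | row > shape[2] | col < 1 | col > shape[3]
  if (any(bad)) {
    stop(sprintf("rendering error: particles outside image bounds: %s",
                 paste(sort(unique(tr$particle[bad])), collapse = ", ")))
  }
  amp <- rep_len(amplitude, max(tr$particle))
  sl <- params$psf_sigma_lateral
  frames <- array(0, dim = c(n_frames, shape[2], shape[3]))
  expected <- array(params$background_level,
                    dim = c(n_frames, shape[2], shape[3]))
  hl <- ceiling(5 * sl)
  for (k in seq_len(nrow(tr))) {
    f <- tr$frame[k]
    yi <- max(1, floor(row[k] - hl)):min(shape[2], ceiling(row[k] + hl))
    xi <- max(1, floor(col[k] - hl)):min(shape[3], ceiling(col[k] + hl))
    gy <- exp(-(yi - row[k])^2 / (2 * sl^2))
    gx <- exp(-(xi - col[k])^2 / (2 * sl^2))
    expected[f, yi, xi] <- expected[f, yi, xi] + amp[tr$particle[k]] * (gy %o% gx)
  }
  withr::with_seed(as.integer(seed), {
    frames <- .apply_camera(expected, params$read_noise_sd, params$bit_depth,
                            shot_noise)
  })
  time_lapse(frames, frame_interval = truth$frame_interval, pixel_size = px)
}
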
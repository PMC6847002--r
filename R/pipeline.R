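#' Pipeline configuration
#'
#' Collects every tunable parameter of the locus and dynamics pipelines in
#' one nested list. Defaults are the published analysis settings wherever one
#' exists: rolling-ball radius 2, 5x5x5 detection cube, 7x7x7 colocalization
#' cube, co-movement tracking gates (linking 0.5 um, no gap closing, 10 fps),
#' diffusion tracking gates (linking 0.1 um, gap closing 0.4 um over up to 4
#' frames, 50 fps), MSD fits on the first 25% of lags with at least 15 lags
#' and R-squared > 0.8, and the diffusive/directed bound alpha = 1.2.
#'
#' @param acquisition An [acquisition_params()] object.
#' @param seed Integer seed recorded with every run.
#' @param ... Named overrides for any of the `detection`, `colocalization`,
#'   `tracking`, `dynamics` sublists (replace whole entries, e.g.
#'   `detection = list(...)`).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(acquisition = acquisition_params(), seed = 1L,
                            ...) {
  cfg <- list(
    acquisition = acquisition,
    detection = list(rolling_ball_radius = 2, sigma_lateral = 2,
                     sigma_axial = 1, threshold = NULL, threshold_k = 6,
                     noise_tolerance = 0, cube_halfwidth = 2),
    colocalization = list(cube_halfwidth = 3),
    tracking = list(
      sigma = 2, threshold = NULL, pair_gate = 0.5,
      comove = list(linking_max_distance = 0.5, gap_max_distance = 0,
                    max_frame_gap = 0, fps = 10),
      diffusion = list(linking_max_distance = 0.1, gap_max_distance = 0.4,
                       max_frame_gap = 4, fps = 50)),
    dynamics = list(fit_fraction = 0.25, min_lags = 15, r2_min = 0.8,
                    alpha_threshold = 1.2),
    seed = as.integer(seed)
  )
  over <- list(...)
  for (nm in names(over)) {
    if (!nm %in% names(cfg)) stop("unknown config section: ", nm)
    cfg[[nm]] <- utils::modifyList(cfg[[nm]], over[[nm]])
  }
  structure(cfg, class = "pipeline_config")
}

#' Serialize / parse a pipeline configuration (YAML)
#'
#' @param config A `pipeline_config`.
#' @param path YAML file path.
#' @return `write_config` invisibly returns `path`; `read_config` returns a
#'   `pipeline_config` identical to the one written.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  x <- unclass(config)
  x$acquisition <- unclass(x$acquisition)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  acq <- do.call(acquisition_params, x$acquisition)
  cfg <- pipeline_config(acquisition = acq, seed = x$seed)
  # assign in place so key order (and NULL-valued keys dropped by YAML,
  # e.g. the auto-threshold) keep their default positions
  for (nm in c("detection", "colocalization", "tracking", "dynamics")) {
    # single-bracket assignment so NULL values (auto thresholds) survive
    for (k in names(x[[nm]])) cfg[[nm]][k] <- x[[nm]][k]
  }
  cfg
}

#' Run the locus pipeline: z-stacks to loci, colocalization and SNR
#'
#' For each channel stack: background subtraction, 3D LoG filtering,
#' per-slice maxima, the 5x5x5 cube test, per-nucleus counting, and per-locus
#' SNR measured on the raw slice holding the locus. When two channels are
#' given (the first is treated as the MB/FRET channel, the second as the
#' EGFP reference), the 7x7x7 colocalization percentage is also computed.
#' Deterministic for a fixed configuration.
#'
#' @param config A [pipeline_config()].
#' @param stacks A list of 1 or 2 [image_stack()] objects, or a character
#'   vector of TIFF paths (read with the configured voxel sizes). Order:
#'   MB/FRET first, reference second.
#' @param roi A labeled integer mask matrix (0 = background), a list of
#'   [nucleus_roi()], a single logical mask, or `NULL` for the whole field.
#' @return A list of class `results_bundle`: `loci` (data frame with a
#'   `channel` column), `counts` (per channel x nucleus, when ROIs are
#'   given), `colocalization` (a `coloc_result` or `NULL`), `snr` (per-locus
#'   table), and `metadata` (config echo and timestamp-free run info).
#' @export
run_locus_pipeline <- function(config, stacks, roi = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  acq <- config$acquisition
  if (is.character(stacks)) {
    stacks <- lapply(stacks, read_stack, z_step = acq$z_step,
                     pixel_size = acq$pixel_size)
  }
  if (inherits(stacks, "image_stack")) stacks <- list(stacks)
  stopifnot(length(stacks) %in% c(1L, 2L))
  channels <- if (length(stacks) == 2) c("MB", "reference") else "MB"
  rois <- .normalize_rois(roi, dim(stacks[[1]]$voxels)[2],
                          dim(stacks[[1]]$voxels)[3])
  det <- config$detection
  per_channel <- vector("list", length(stacks))
  for (ch in seq_along(stacks)) {
    loci_all <- list()
    if (is.null(rois)) {
      l <- .stage(sprintf("detection[%s]", channels[ch]), detect_loci,
                  stacks[[ch]], roi = NULL,
                  rolling_ball_radius = det$rolling_ball_radius,
                  sigma_lateral = det$sigma_lateral,
                  sigma_axial = det$sigma_axial,
                  threshold = det$threshold, threshold_k = det$threshold_k,
                  noise_tolerance = det$noise_tolerance,
                  cube_halfwidth = det$cube_halfwidth)
      if (nrow(l)) l$nucleus_id <- NA_integer_
      loci_all[[1]] <- l
    } else {
      for (r in rois) {
        l <- .stage(sprintf("detection[%s, nucleus %d]", channels[ch],
                            r$nucleus_id),
                    detect_loci, stacks[[ch]], roi = r,
                    rolling_ball_radius = det$rolling_ball_radius,
                    sigma_lateral = det$sigma_lateral,
                    sigma_axial = det$sigma_axial,
                    threshold = det$threshold, threshold_k = det$threshold_k,
                    noise_tolerance = det$noise_tolerance,
                    cube_halfwidth = det$cube_halfwidth)
        if (nrow(l)) l$nucleus_id <- r$nucleus_id
        loci_all[[length(loci_all) + 1L]] <- l
      }
    }
    loci <- do.call(rbind, loci_all[vapply(loci_all, nrow, 0L) > 0])
    if (is.null(loci)) {
      loci <- data.frame(z = integer(), y = integer(), x = integer(),
                         intensity = numeric(), nucleus_id = integer())
    }
    loci$channel <- if (nrow(loci)) channels[ch] else character(0)
    per_channel[[ch]] <- loci
  }
  loci <- do.call(rbind, per_channel)
  rownames(loci) <- NULL
  counts <- NULL
  if (!is.null(rois)) {
    counts <- do.call(rbind, lapply(seq_along(stacks), function(ch) {
      cc <- count_loci(per_channel[[ch]], rois)
      cc$channel <- channels[ch]
      cc
    }))
  }
  coloc <- NULL
  if (length(stacks) == 2 && nrow(per_channel[[1]]) > 0) {
    coloc <- .stage("colocalization", colocalize_3d,
                    per_channel[[1]], per_channel[[2]],
                    cube_halfwidth = config$colocalization$cube_halfwidth)
  }
  snr <- .snr_table(per_channel, stacks, channels)
  structure(
    list(loci = loci, counts = counts, colocalization = coloc, snr = snr,
         metadata = list(config = unclass(config), seed = config$seed,
                         n_channels = length(stacks),
                         package_version = as.character(
                           utils::packageVersion("spotloci")))),
    class = "results_bundle")
}

.normalize_rois <- function(roi, nr, nc) {
  if (is.null(roi)) return(NULL)
  if (is.matrix(roi) && (is.numeric(roi) || is.integer(roi)) &&
      any(roi > 1)) {
    return(split_labeled_mask(roi))
  }
  if (is.matrix(roi)) return(list(nucleus_roi(roi, 1L)))
  if (inherits(roi, "nucleus_roi")) return(list(roi))
  if (is.list(roi)) return(roi)
  stop("unsupported ROI input")
}

# run one stage, rethrowing errors with the stage name attached
.stage <- function(name, fun, ...) {
  tryCatch(fun(...), error = function(e) {
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

.snr_table <- function(per_channel, stacks, channels) {
  rows <- list()
  for (ch in seq_along(stacks)) {
    loci <- per_channel[[ch]]
    if (!nrow(loci)) next
    for (i in seq_len(nrow(loci))) {
      slice <- stacks[[ch]]$voxels[loci$z[i], , , drop = TRUE]
      m <- tryCatch(
        compute_snr(slice, c(loci$y[i], loci$x[i])),
        error = function(e) data.frame(spot_max = NA_real_,
                                       bg_mean = NA_real_, bg_sd = NA_real_,
                                       snr = NA_real_))
      m$channel <- channels[ch]
      m$z <- loci$z[i]; m$y <- loci$y[i]; m$x <- loci$x[i]
      rows[[length(rows) + 1L]] <- m
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(spot_max = numeric(), bg_mean = numeric(),
                      bg_sd = numeric(), snr = numeric(),
                      channel = character(), z = integer(), y = integer(),
                      x = integer())
  }
  rownames(out) <- NULL
  out
}

#' Run the dynamics pipeline: movies to tracks, co-movement or diffusion
#'
#' `mode = "comove"` expects two movies (reference/EGFP first, MB/FRET
#' second) acquired simultaneously: peaks are detected and linked with the
#' co-movement gates (linking 0.5 um, no gap closing), tracks are paired
#' across channels by mutual nearest neighbors, and the co-movement
#' cross-correlation coefficient is computed per pair. `mode = "diffusion"`
#' expects one movie: peaks are linked with the diffusion gates (0.1 um),
#' gaps are closed (0.4 um, up to 4 frames), and each track receives an MSD
#' power-law fit and motion classification.
#'
#' @param config A [pipeline_config()].
#' @param movies A list of [time_lapse()] objects or a character vector of
#'   TIFF paths.
#' @param mode `"comove"` or `"diffusion"`.
#' @return A `results_bundle` list: `tracks` (per channel), plus
#'   `co_movement` (per-pair rho table) or `msd_fits` (per-track table).
#' @export
run_dynamics_pipeline <- function(config, movies,
                                  mode = c("comove", "diffusion")) {
  mode <- match.arg(mode)
  stopifnot(inherits(config, "pipeline_config"))
  acq <- config$acquisition
  trk <- config$tracking
  gates <- trk[[if (mode == "comove") "comove" else "diffusion"]]
  fi <- 1 / gates$fps
  if (is.character(movies)) {
    movies <- lapply(movies, read_movie, frame_interval = fi,
                     pixel_size = acq$pixel_size)
  }
  if (inherits(movies, "time_lapse")) movies <- list(movies)
  n_expected <- if (mode == "comove") 2L else 1L
  stopifnot(length(movies) == n_expected)
  tracks <- lapply(seq_along(movies), function(i) {
    pk <- .stage(sprintf("peak detection[channel %d]", i), detect_peaks_2d,
                 movies[[i]], sigma = trk$sigma, threshold = trk$threshold)
    if (nrow(pk) == 0) return(pk[, c("frame", "x", "y")][0, ])
    tr <- .stage("linking", link_frames, pk, gates$linking_max_distance)
    tr <- .stage("gap closing", close_gaps, tr, gates$gap_max_distance,
                 gates$max_frame_gap)
    filter_tracks(tr, 2)
  })
  meta <- list(config = unclass(config), seed = config$seed, mode = mode,
               package_version = as.character(utils::packageVersion("spotloci")))
  if (all(vapply(tracks, nrow, 0L) == 0)) {
    warning("no tracks detected: empty bundle")
    return(structure(list(tracks = tracks, co_movement = NULL,
                          msd_fits = NULL, metadata = meta),
                     class = "results_bundle"))
  }
  if (mode == "comove") {
    pairs <- pair_channels(tracks[[1]], tracks[[2]], gate = trk$pair_gate)
    rho <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(k) {
      ta <- tracks[[1]][tracks[[1]]$track_id == pairs$track_a[k], ]
      tb <- tracks[[2]][tracks[[2]]$track_id == pairs$track_b[k], ]
      cm <- tryCatch(co_movement_coefficient(ta, tb, pair_id = k),
                     error = function(e) NULL)
      if (is.null(cm)) return(NULL)
      data.frame(pair_id = k, track_a = pairs$track_a[k],
                 track_b = pairs$track_b[k], rho = cm$rho,
                 n_frames_used = cm$n_frames_used)
    }))
    structure(list(tracks = tracks, co_movement = rho, msd_fits = NULL,
                   metadata = meta), class = "results_bundle")
  } else {
    dyn <- config$dynamics
    fits <- fit_all_tracks(tracks[[1]], fi, dyn$fit_fraction, dyn$min_lags,
                           dyn$r2_min, dyn$alpha_threshold)
    structure(list(tracks = tracks, co_movement = NULL, msd_fits = fits,
                   metadata = meta), class = "results_bundle")
  }
}

#' Mass ratio of two molecular complexes, as a percentage
#'
#' Reporting utility for comparing the total mass of two labeling complexes,
#' e.g. a dCas9 + sgRNA + two-molecular-beacon imaging complex (~242 kDa)
#' against an MS2-aptamer system carrying 32 coat-protein fusions
#' (~1760 kDa): 100 * 242 / 1760 = 13.75, reported as 14%.
#'
#' @param mass_a,mass_b Masses in the same units (kDa), both > 0.
#' @return A list of class `mass_ratio` with `percent` (unrounded) and
#'   `percent_rounded` (nearest integer).
#' @export
mass_ratio_percent <- function(mass_a, mass_b) {
  if (!(is.numeric(mass_a) && is.numeric(mass_b) && mass_a > 0 && mass_b > 0)) {
    stop("masses must be positive numbers")
  }
  pct <- 100 * mass_a / mass_b
  structure(list(percent = pct, percent_rounded = round(pct)),
            class = "mass_ratio")
}

#' @export
print.mass_ratio <- function(x, ...) {
  cat(sprintf("mass ratio: %.4g%% (reported as %d%%)\n",
              x$percent, x$percent_rounded))
  invisible(x)
}
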
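#' Signal-to-noise ratio of a detected spot
#'
#' Computes `SNR = (spot_max - bg_mean) / bg_sd` on a raw (unfiltered) 2D
#' image: `spot_max` is the maximum intensity within `spot_radius` pixels of
#' the spot position, and the background mean and standard deviation are
#' taken either over an annulus around the spot (default, inner/outer radii
#' `bg_annulus`) or over an explicit background mask such as the nucleus
#' minus all spots. The statistic is invariant under any affine intensity
#' transform with positive gain.
#'
#' @param image Numeric matrix of raw intensities.
#' @param spot Numeric `c(row, col)` spot position (may be subpixel).
#' @param spot_radius Radius in pixels of the disc searched for the spot
#'   maximum (default 3).
#' @param bg_annulus Numeric `c(r_in, r_out)` annulus radii in pixels
#'   (default `c(5, 10)`); `r_in` must exceed `spot_radius` and the annulus
#'   must contain at least 20 in-image pixels.
#' @param bg_mask Optional logical matrix selecting background pixels
#'   directly; overrides `bg_annulus`.
#' @return A one-row data frame with columns `spot_max`, `bg_mean`, `bg_sd`,
#'   `snr`.
#' @export
compute_snr <- function(image, spot, spot_radius = 3, bg_annulus = c(5, 10),
                        bg_mask = NULL) {
  stopifnot(is.matrix(image), length(spot) == 2, spot_radius > 0)
  nr <- nrow(image); nc <- ncol(image)
  d <- sqrt(outer((seq_len(nr) - spot[1])^2, (seq_len(nc) - spot[2])^2, "+"))
  in_spot <- d <= spot_radius
  if (!any(in_spot)) stop("spot disc contains no pixels")
  if (is.null(bg_mask)) {
    stopifnot(length(bg_annulus) == 2, bg_annulus[1] < bg_annulus[2])
    if (bg_annulus[1] <= spot_radius) {
      stop("annulus inner radius must exceed spot_radius")
    }
    bg_mask <- d > bg_annulus[1] & d <= bg_annulus[2]
  } else {
    stopifnot(is.matrix(bg_mask), nrow(bg_mask) == nr, ncol(bg_mask) == nc)
    bg_mask <- bg_mask & !in_spot
  }
  if (sum(bg_mask) < 20) stop("background region must contain at least 20 pixels")
  bg <- image[bg_mask]
  bg_mean <- mean(bg)
  bg_sd <- stats::sd(bg)
  if (bg_sd == 0) stop("degenerate background: zero standard deviation")
  spot_max <- max(image[in_spot])
  data.frame(spot_max = spot_max, bg_mean = bg_mean, bg_sd = bg_sd,
             snr = (spot_max - bg_mean) / bg_sd)
}
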
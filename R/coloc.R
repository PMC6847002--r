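#' Two-channel 3D colocalization by the voxel-cube criterion
#'
#' A locus detected in the molecular-beacon (MB/FRET) channel counts as one
#' colocalization event if at least one reference-channel (EGFP) locus lies
#' within a `(2h+1)^3` voxel cube centered on it (default `h = 3`, a 7x7x7
#' cube). Cube membership is the per-axis (Chebyshev) test
#' `|dz| <= h & |dy| <= h & |dx| <= h`, matching a voxel cube literally. Each
#' MB locus contributes at most one event however many reference loci fall in
#' its cube; a single reference locus may satisfy several MB loci (no
#' one-to-one matching is imposed). The percentage is normalized by the
#' number of MB loci only, so swapping the channels changes the result.
#'
#' @param mb_loci Data frame of MB-channel loci with columns `z`, `y`, `x`
#'   (from [detect_loci()] / [select_3d_maxima()]); must be non-empty.
#' @param ref_loci Data frame of reference-channel loci, same columns; both
#'   channels must come from stacks of identical geometry.
#' @param cube_halfwidth Cube half-width `h >= 0` in voxels (default 3).
#' @return An object of class `coloc_result`: a list with `n_mb_maxima`,
#'   `n_coloc_events`, `percent_coloc`, and `pairs` (a data frame matching
#'   each colocalized MB locus to its nearest reference locus by Euclidean
#'   voxel distance, ties broken by reference scan order).
#' @export
colocalize_3d <- function(mb_loci, ref_loci, cube_halfwidth = 3) {
  stopifnot(cube_halfwidth >= 0)
  h <- cube_halfwidth
  if (is.null(mb_loci) || nrow(mb_loci) == 0) {
    stop("no MB maxima: colocalization percentage is undefined for an empty MB channel")
  }
  n_ref <- if (is.null(ref_loci)) 0L else nrow(ref_loci)
  pairs <- data.frame(mb_z = integer(), mb_y = integer(), mb_x = integer(),
                      ref_z = integer(), ref_y = integer(), ref_x = integer(),
                      distance = numeric())
  events <- 0L
  if (n_ref > 0) {
    # reference scan order for deterministic tie-breaking
    o <- order(ref_loci$z, ref_loci$y, ref_loci$x)
    ref <- ref_loci[o, ]
    for (i in seq_len(nrow(mb_loci))) {
      dz <- ref$z - mb_loci$z[i]
      dy <- ref$y - mb_loci$y[i]
      dx <- ref$x - mb_loci$x[i]
      inside <- abs(dz) <= h & abs(dy) <= h & abs(dx) <= h
      if (any(inside)) {
        events <- events + 1L
        d2 <- dz[inside]^2 + dy[inside]^2 + dx[inside]^2
        j <- which(inside)[which.min(d2)]
        pairs <- rbind(pairs, data.frame(
          mb_z = mb_loci$z[i], mb_y = mb_loci$y[i], mb_x = mb_loci$x[i],
          ref_z = ref$z[j], ref_y = ref$y[j], ref_x = ref$x[j],
          distance = sqrt(min(d2))))
      }
    }
  }
  structure(
    list(n_mb_maxima = nrow(mb_loci),
         n_coloc_events = events,
         percent_coloc = 100 * events / nrow(mb_loci),
         pairs = pairs,
         cube_halfwidth = h),
    class = "coloc_result"
  )
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf(
    "3D colocalization (%dx%dx%d cube): %d / %d MB maxima colocalized (%.1f%%)\n",
    2 * x$cube_halfwidth + 1, 2 * x$cube_halfwidth + 1,
    2 * x$cube_halfwidth + 1,
    x$n_coloc_events, x$n_mb_maxima, x$percent_coloc))
  invisible(x)
}
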
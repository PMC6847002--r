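#' Detect subpixel 2D peaks in every movie frame
#'
#' Applies a 2D Laplacian-of-Gaussian filter to each frame, finds interior
#' supra-threshold local maxima (the same 8-neighbor rule as the z-stack
#' detector), and refines each to subpixel precision by an intensity-weighted
#' centroid of the (non-negative) filter response over a
#' `(2 ceil(sigma) + 1)^2` window. Positions are returned in micrometres with
#' pixel centers at `(col - 1) * pixel_size`, `(row - 1) * pixel_size`.
#'
#' @param movie A [time_lapse()] object.
#' @param sigma LoG sigma in pixels (default 2).
#' @param threshold Threshold on the filter response, or `NULL` for a
#'   per-frame `median + 6 * MAD` rule.
#' @return Data frame with columns `frame`, `x`, `y` (um), `row`, `col`
#'   (nearest-pixel indices) and `intensity` (peak filter response).
#' @export
detect_peaks_2d <- function(movie, sigma = 2, threshold = NULL) {
  stopifnot(inherits(movie, "time_lapse"), sigma > 0)
  px <- movie$pixel_size
  h <- ceiling(sigma)
  out <- vector("list", dim(movie$frames)[1])
  for (f in seq_len(dim(movie$frames)[1])) {
    m <- movie$frames[f, , , drop = TRUE]
    resp <- .log_filter_2d(m, sigma)
    thr <- if (is.null(threshold)) {
      # floor keeps float residue of featureless frames below threshold
      max(stats::median(resp) + 6 * stats::mad(resp), 1e-8 * max(abs(m)))
    } else threshold
    mx <- .local_maxima_2d(resp, thr, 0)
    if (!nrow(mx)) next
    pos <- t(vapply(seq_len(nrow(mx)), function(i) {
      .centroid_refine(resp, mx$row[i], mx$col[i], h)
    }, numeric(2)))
    out[[f]] <- data.frame(
      frame = f,
      x = (pos[, 2] - 1) * px, y = (pos[, 1] - 1) * px,
      row = mx$row, col = mx$col, intensity = mx$intensity)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(frame = integer(), x = numeric(), y = numeric(),
                      row = integer(), col = integer(), intensity = numeric())
  }
  rownames(res) <- NULL
  res
}

# intensity-weighted centroid over a (2h+1)^2 window of the response clipped
# at zero; returns c(row, col) in subpixel units
.centroid_refine <- function(resp, row, col, h) {
  ri <- max(1, row - h):min(nrow(resp), row + h)
  ci <- max(1, col - h):min(ncol(resp), col + h)
  w <- pmax(resp[ri, ci, drop = FALSE], 0)
  sw <- sum(w)
  if (sw <= 0) return(c(row, col))
  c(sum(ri * rowSums(w)), sum(ci * colSums(w))) / sw
}

#' Link per-frame peaks into tracks (linear-assignment tracker)
#'
#' For each consecutive frame pair, solves a rectangular linear assignment
#' problem whose costs are squared displacements for candidate links with
#' distance at most `linking_max_distance` and whose no-link alternative
#' costs `(1.05 * linking_max_distance)^2`, so that total squared
#' displacement is minimized over all feasible assignments. Unlinked peaks
#' start new tracks. Within each frame, peaks are processed in (x, y) order,
#' making the result independent of input-row ordering.
#'
#' @param peaks Data frame from [detect_peaks_2d()] (columns `frame`, `x`,
#'   `y`, optionally `intensity`).
#' @param linking_max_distance Gating distance in um (> 0).
#' @return Data frame with columns `track_id`, `frame`, `x`, `y`
#'   (one row per retained peak; every input peak appears in exactly one
#'   track).
#' @export
link_frames <- function(peaks, linking_max_distance) {
  stopifnot(linking_max_distance > 0)
  if (is.null(peaks) || nrow(peaks) == 0) {
    return(data.frame(track_id = integer(), frame = integer(),
                      x = numeric(), y = numeric()))
  }
  peaks <- peaks[order(peaks$frame, peaks$x, peaks$y), , drop = FALSE]
  frames <- sort(unique(peaks$frame))
  gate2 <- linking_max_distance^2
  next_id <- 0L
  new_ids <- function(k) {
    ids <- next_id + seq_len(k)
    next_id <<- next_id + k
    ids
  }
  cur <- peaks[peaks$frame == frames[1], , drop = FALSE]
  cur$track_id <- new_ids(nrow(cur))
  rows <- list(cur[, c("track_id", "frame", "x", "y")])
  for (fi in seq_along(frames)[-1]) {
    nxt <- peaks[peaks$frame == frames[fi], , drop = FALSE]
    nxt$track_id <- NA_integer_
    if (frames[fi] == frames[fi - 1] + 1 && nrow(cur) > 0) {
      d2 <- outer(cur$x, nxt$x, "-")^2 + outer(cur$y, nxt$y, "-")^2
      cost <- ifelse(d2 <= gate2, d2, Inf)
      match <- .lap_match(cost, linking_max_distance)
      linked <- which(!is.na(match))
      nxt$track_id[match[linked]] <- cur$track_id[linked]
    }
    unlinked <- is.na(nxt$track_id)
    nxt$track_id[unlinked] <- new_ids(sum(unlinked))
    rows[[length(rows) + 1L]] <- nxt[, c("track_id", "frame", "x", "y")]
    cur <- nxt
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$track_id, out$frame), ]
  rownames(out) <- NULL
  out
}

#' Close temporal gaps by merging track ends with later track starts
#'
#' Solves a second linear assignment between track ends and later track
#' starts: an end may be merged with a start if the frame gap is in
#' `[1, max_frame_gap]` and the end-to-start distance is at most
#' `gap_max_distance`; costs are squared distances with the same
#' `(1.05 * gate)^2` no-link alternative. Merging is applied transitively
#' (chains of merges form one track). With both gates 0 — the co-movement
#' parameter set — the input is returned unchanged.
#'
#' @param tracks Track table from [link_frames()].
#' @param gap_max_distance Maximum end-to-start distance in um (>= 0).
#' @param max_frame_gap Maximum number of skipped frames (>= 0).
#' @return A track table in the same format; merged tracks keep the id of
#'   their earliest segment and retain missing frames as gaps.
#' @export
close_gaps <- function(tracks, gap_max_distance, max_frame_gap) {
  stopifnot(gap_max_distance >= 0, max_frame_gap >= 0)
  if (gap_max_distance == 0 || max_frame_gap == 0) return(tracks)
  ids <- sort(unique(tracks$track_id))
  if (length(ids) < 2) return(tracks)
  first <- do.call(rbind, lapply(ids, function(i) {
    tr <- tracks[tracks$track_id == i, ]
    tr[which.min(tr$frame), ]
  }))
  last <- do.call(rbind, lapply(ids, function(i) {
    tr <- tracks[tracks$track_id == i, ]
    tr[which.max(tr$frame), ]
  }))
  # frame difference start - end in [2, max_frame_gap + 1] skips 1..max_frame_gap
  # frames; difference 1 would be an ordinary link, not a gap
  fdiff <- outer(last$frame, first$frame, function(e, s) s - e)
  d2 <- outer(last$x, first$x, "-")^2 + outer(last$y, first$y, "-")^2
  feasible <- fdiff >= 2 & fdiff <= max_frame_gap + 1 & d2 <= gap_max_distance^2
  diag(feasible) <- FALSE
  if (!any(feasible)) return(tracks)
  cost <- ifelse(feasible, d2, Inf)
  match <- .lap_match(cost, gap_max_distance)
  # follow merge chains: successor[i] = index of track whose start continues i
  successor <- match
  has_pred <- rep(FALSE, length(ids))
  has_pred[successor[!is.na(successor)]] <- TRUE
  remap <- seq_along(ids)
  for (i in order(first$frame)) {
    if (!has_pred[i]) {
      j <- successor[i]
      while (!is.na(j)) {
        remap[j] <- remap[i]
        j <- successor[j]
      }
    }
  }
  tracks$track_id <- ids[remap[match(tracks$track_id, ids)]]
  tracks <- tracks[order(tracks$track_id, tracks$frame), ]
  rownames(tracks) <- NULL
  tracks
}

#' Frames missing inside a track (its gaps)
#'
#' @param track One track's rows of a track table.
#' @return Integer vector of frame indices absent between the track's first
#'   and last frame.
#' @export
track_gaps <- function(track) {
  setdiff(seq(min(track$frame), max(track$frame)), track$frame)
}

#' Drop tracks too short for downstream analysis
#'
#' @param tracks Track table.
#' @param min_points Minimum number of points (default 2).
#' @return Filtered track table.
#' @export
filter_tracks <- function(tracks, min_points = 2) {
  n <- table(tracks$track_id)
  keep <- names(n)[n >= min_points]
  out <- tracks[tracks$track_id %in% as.integer(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pair tracks across two channels by mutual nearest neighbors
#'
#' Computes each track's time-averaged position and pairs channel-A with
#' channel-B tracks that are mutual nearest neighbors, rejecting pairs whose
#' centroid distance exceeds `gate`.
#'
#' @param tracks_a,tracks_b Track tables for the two channels (shared
#'   geometry and frame times).
#' @param gate Maximum centroid distance in um (default 0.5, mirroring the
#'   co-movement linking gate).
#' @return Data frame with columns `pair_id`, `track_a`, `track_b`,
#'   `distance`.
#' @export
pair_channels <- function(tracks_a, tracks_b, gate = 0.5) {
  empty <- data.frame(pair_id = integer(), track_a = integer(),
                      track_b = integer(), distance = numeric())
  if (nrow(tracks_a) == 0 || nrow(tracks_b) == 0) {
    warning("empty channel: no track pairs")
    return(empty)
  }
  cent <- function(tr) {
    ids <- sort(unique(tr$track_id))
    data.frame(
      track_id = ids,
      x = vapply(ids, function(i) mean(tr$x[tr$track_id == i]), 1),
      y = vapply(ids, function(i) mean(tr$y[tr$track_id == i]), 1))
  }
  ca <- cent(tracks_a); cb <- cent(tracks_b)
  d <- sqrt(outer(ca$x, cb$x, "-")^2 + outer(ca$y, cb$y, "-")^2)
  nn_ab <- apply(d, 1, which.min)
  nn_ba <- apply(d, 2, which.min)
  pairs <- empty
  for (i in seq_len(nrow(ca))) {
    j <- nn_ab[i]
    if (nn_ba[j] == i && d[i, j] <= gate) {
      pairs <- rbind(pairs, data.frame(
        pair_id = nrow(pairs) + 1L,
        track_a = ca$track_id[i], track_b = cb$track_id[j],
        distance = d[i, j]))
    }
  }
  pairs
}
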
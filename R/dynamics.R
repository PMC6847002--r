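#' Co-movement cross-correlation coefficient of a track pair
#'
#' Computes the normalized cross-correlation between the 2D position-vector
#' sequences of two paired trajectories over their common frames:
#' numerator `<r_A . r_B> - <r_A> . <r_B>` (means of/over dot products),
#' denominator the square root of the product of the per-track
#' position-variance terms `<|r|^2> - |<r>|^2`. The coefficient is 1 for
#' perfectly co-moving trajectories, -1 for completely anticorrelated ones,
#' and is invariant under a common rigid translation of both tracks. A
#' displacement-based variant (same formula applied to frame-to-frame
#' displacement vectors) is available via `method = "displacement"`.
#'
#' @param track_a,track_b Track tables (columns `frame`, `x`, `y`) for one
#'   track each; only frames common to both are used (at least 3 required).
#' @param method `"position"` (default; the formula applied to position
#'   vectors) or `"displacement"`.
#' @param pair_id Optional identifier carried through to the result.
#' @return A list of class `co_movement` with elements `rho`,
#'   `n_frames_used`, `method`, `pair_id`.
#' @export
co_movement_coefficient <- function(track_a, track_b,
                                    method = c("position", "displacement"),
                                    pair_id = NA_integer_) {
  method <- match.arg(method)
  common <- intersect(track_a$frame, track_b$frame)
  if (length(common) < 3) stop("tracks share fewer than 3 common frames")
  a <- track_a[match(sort(common), track_a$frame), ]
  b <- track_b[match(sort(common), track_b$frame), ]
  ax <- a$x; ay <- a$y; bx <- b$x; by <- b$y
  if (method == "displacement") {
    ax <- diff(ax); ay <- diff(ay); bx <- diff(bx); by <- diff(by)
  }
  num <- mean(ax * bx + ay * by) - (mean(ax) * mean(bx) + mean(ay) * mean(by))
  var_a <- mean(ax^2 + ay^2) - (mean(ax)^2 + mean(ay)^2)
  var_b <- mean(bx^2 + by^2) - (mean(bx)^2 + mean(by)^2)
  if (var_a <= 0 || var_b <= 0) {
    stop("degenerate (stationary) track: zero position variance")
  }
  structure(list(rho = num / sqrt(var_a * var_b),
                 n_frames_used = length(common),
                 method = method, pair_id = pair_id),
            class = "co_movement")
}

#' @export
print.co_movement <- function(x, ...) {
  cat(sprintf("co-movement rho = %.4f (%d common frames, %s vectors)\n",
              x$rho, x$n_frames_used, x$method))
  invisible(x)
}

#' Time-averaged mean squared displacement of one track
#'
#' For each integer lag `k`, averages the squared 2D displacement over all
#' point pairs of the track separated by exactly `k` frames; lags with no
#' pairs (because of gaps) are omitted. Lag times are `k * frame_interval`.
#'
#' @param track Track table rows of a single track (columns `frame`, `x`,
#'   `y`, at least 2 points).
#' @param frame_interval Seconds per frame.
#' @return Data frame of class `msd_curve` with columns `lag_frames`, `lag`
#'   (s), `msd` (um^2), `n_pairs`.
#' @export
compute_msd <- function(track, frame_interval) {
  stopifnot(nrow(track) >= 2, frame_interval > 0)
  o <- order(track$frame)
  f <- track$frame[o]; x <- track$x[o]; y <- track$y[o]
  if (any(duplicated(f))) stop("track has duplicated frames")
  maxlag <- max(f) - min(f)
  lags <- integer(0); msd <- numeric(0); np <- integer(0)
  for (k in seq_len(maxlag)) {
    j <- match(f + k, f)
    ok <- !is.na(j)
    if (!any(ok)) next
    d2 <- (x[j[ok]] - x[ok])^2 + (y[j[ok]] - y[ok])^2
    lags <- c(lags, k); msd <- c(msd, mean(d2)); np <- c(np, sum(ok))
  }
  out <- data.frame(lag_frames = lags, lag = lags * frame_interval,
                    msd = msd, n_pairs = np)
  class(out) <- c("msd_curve", "data.frame")
  attr(out, "frame_interval") <- frame_interval
  out
}

#' Power-law fit of an MSD curve
#'
#' Fits `MSD = 4 D_eff * lag^alpha` by ordinary least squares of `log(msd)`
#' on `log(lag)` over the first `ceil(fit_fraction * n_lags)` available lags
#' (at least 2): the slope is the diffusive exponent `alpha` and the
#' intercept gives `D_eff = exp(intercept) / 4`. R-squared is computed on the
#' fitted window. A track is rejected when it offers fewer than `min_lags`
#' lags, when the fit's R-squared does not exceed `r2_min`, or when a zero
#' MSD value makes the log transform undefined; otherwise it is classified
#' by [classify_motion()].
#'
#' @param curve An `msd_curve` from [compute_msd()].
#' @param fit_fraction Fraction of available lags used for the fit
#'   (default 0.25).
#' @param min_lags Minimum number of available lags for a track to be
#'   fitted at all (default 15).
#' @param r2_min Minimum R-squared for an accepted fit (default 0.8).
#' @param alpha_threshold Classification bound passed to [classify_motion()]
#'   (default 1.2).
#' @return A list of class `msd_fit` with `d_eff` (um^2/s), `alpha`,
#'   `r_squared`, `n_lags_fit`, `n_lags`, `motion_class`
#'   (`"diffusive"`, `"directed"` or `"rejected"`), `reason` (for rejects).
#' @export
fit_msd <- function(curve, fit_fraction = 0.25, min_lags = 15, r2_min = 0.8,
                    alpha_threshold = 1.2) {
  stopifnot(inherits(curve, "msd_curve") || is.data.frame(curve),
            fit_fraction > 0, fit_fraction <= 1)
  n_lags <- nrow(curve)
  mk <- function(d_eff = NA_real_, alpha = NA_real_, r2 = NA_real_,
                 nfit = NA_integer_, class = "rejected", reason = NA_character_) {
    structure(list(d_eff = d_eff, alpha = alpha, r_squared = r2,
                   n_lags_fit = nfit, n_lags = n_lags,
                   motion_class = class, reason = reason),
              class = "msd_fit")
  }
  if (n_lags < min_lags) {
    return(mk(reason = sprintf("only %d lags (< %d)", n_lags, min_lags)))
  }
  nfit <- max(2L, as.integer(ceiling(fit_fraction * n_lags)))
  win <- curve[seq_len(nfit), ]
  if (any(win$msd <= 0)) {
    return(mk(nfit = nfit, reason = "zero MSD in fit window (log undefined)"))
  }
  lx <- log(win$lag); ly <- log(win$msd)
  fit <- stats::lm.fit(cbind(1, lx), ly)
  alpha <- fit$coefficients[2]
  d_eff <- exp(fit$coefficients[1]) / 4
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((ly - mean(ly))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else as.numeric(ss_res < 1e-12)
  if (r2 <= r2_min) {
    return(mk(d_eff, alpha, r2, nfit, "rejected",
              sprintf("R^2 = %.3f <= %.3f", r2, r2_min)))
  }
  out <- mk(d_eff, alpha, r2, nfit, class = "accepted")
  out$motion_class <- classify_motion(out, alpha_threshold)$motion_class
  out
}

#' @export
print.msd_fit <- function(x, ...) {
  if (x$motion_class == "rejected") {
    cat(sprintf("MSD fit rejected: %s\n", x$reason))
  } else {
    cat(sprintf(
      "MSD fit: D_eff = %.4g um^2/s, alpha = %.3f, R^2 = %.3f (%d lags) -> %s\n",
      x$d_eff, x$alpha, x$r_squared, x$n_lags_fit, x$motion_class))
  }
  invisible(x)
}

#' Classify a fitted track as diffusive or directed
#'
#' Tracks with diffusive exponent below the threshold (default 1.2) are
#' diffusive; above it, directed transport. A value exactly at the threshold
#' is classed diffusive (tie rule). Rejected fits pass through unchanged.
#'
#' @param fit An `msd_fit` from [fit_msd()].
#' @param alpha_threshold Classification bound (default 1.2).
#' @return The `msd_fit` with `motion_class` set.
#' @export
classify_motion <- function(fit, alpha_threshold = 1.2) {
  stopifnot(inherits(fit, "msd_fit"))
  if (identical(fit$motion_class, "rejected")) return(fit)
  fit$motion_class <- if (fit$alpha > alpha_threshold) "directed" else "diffusive"
  fit
}

#' Fit MSD power laws for every track in a table
#'
#' @param tracks Track table (columns `track_id`, `frame`, `x`, `y`).
#' @param frame_interval Seconds per frame.
#' @inheritParams fit_msd
#' @return Data frame with one row per track: `track_id`, `n_points`,
#'   `n_lags`, `d_eff`, `alpha`, `r_squared`, `motion_class`.
#' @export
fit_all_tracks <- function(tracks, frame_interval, fit_fraction = 0.25,
                           min_lags = 15, r2_min = 0.8,
                           alpha_threshold = 1.2) {
  ids <- sort(unique(tracks$track_id))
  rows <- lapply(ids, function(i) {
    tr <- tracks[tracks$track_id == i, ]
    if (nrow(tr) < 2) return(NULL)
    f <- fit_msd(compute_msd(tr, frame_interval), fit_fraction, min_lags,
                 r2_min, alpha_threshold)
    data.frame(track_id = i, n_points = nrow(tr), n_lags = f$n_lags,
               d_eff = unname(f$d_eff), alpha = unname(f$alpha),
               r_squared = unname(f$r_squared), motion_class = f$motion_class)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(track_id = integer(), n_points = integer(),
                      n_lags = integer(), d_eff = numeric(), alpha = numeric(),
                      r_squared = numeric(), motion_class = character())
  }
  rownames(out) <- NULL
  out
}
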
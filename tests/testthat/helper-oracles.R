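# Independent brute-force oracles and small utilities shared by the tests.
# These deliberately re-derive each rule with plain loops, independent of the
# package's vectorized implementations.

# exhaustive 3D-maximum rule: scan every voxel; a voxel is a locus iff it is
# an interior in-slice 8-neighbor maximum (>= all, > at least one), above
# threshold, inside the ROI, and >= every voxel of its truncated cube; exact
# equal-intensity ties within each other's cubes keep the first in
# (slice, row, col) scan order
brute_force_3d_maxima <- function(v, threshold, h, roi = NULL) {
  d <- dim(v)
  hits <- NULL
  for (z in seq_len(d[1])) for (y in 2:(d[2] - 1)) for (x in 2:(d[3] - 1)) {
    if (!is.null(roi) && !roi[y, x]) next
    val <- v[z, y, x]
    if (val <= threshold) next
    ge_all <- TRUE; gt_one <- FALSE
    for (dy in -1:1) for (dx in -1:1) {
      if (dy == 0 && dx == 0) next
      nb <- v[z, y + dy, x + dx]
      if (val < nb) ge_all <- FALSE
      if (val > nb) gt_one <- TRUE
    }
    if (!ge_all || !gt_one) next
    # plateau representative: skip if an equal-value 8-neighbor candidate
    # precedes it in row-major order within the slice
    plateau_prior <- FALSE
    for (dy in -1:1) for (dx in -1:1) {
      if (dy == 0 && dx == 0) next
      yy <- y + dy; xx <- x + dx
      if (yy < 2 || yy > d[2] - 1 || xx < 2 || xx > d[3] - 1) next
      if (!is.null(roi) && !roi[yy, xx]) next
      if (v[z, yy, xx] == val && (yy < y || (yy == y && xx < x))) {
        # the earlier pixel must itself be a candidate
        ge2 <- TRUE; gt2 <- FALSE
        for (ddy in -1:1) for (ddx in -1:1) {
          if (ddy == 0 && ddx == 0) next
          nb2 <- v[z, yy + ddy, xx + ddx]
          if (v[z, yy, xx] < nb2) ge2 <- FALSE
          if (v[z, yy, xx] > nb2) gt2 <- TRUE
        }
        if (ge2 && gt2) plateau_prior <- TRUE
      }
    }
    if (plateau_prior) next
    cube <- v[max(1, z - h):min(d[1], z + h),
              max(1, y - h):min(d[2], y + h),
              max(1, x - h):min(d[3], x + h)]
    if (val >= max(cube)) hits <- rbind(hits, c(z, y, x, val))
  }
  if (is.null(hits)) {
    return(data.frame(z = integer(), y = integer(), x = integer(),
                      intensity = numeric()))
  }
  hits <- as.data.frame(hits)
  names(hits) <- c("z", "y", "x", "intensity")
  hits <- hits[order(hits$z, hits$y, hits$x), ]
  keep <- rep(TRUE, nrow(hits))
  for (i in seq_len(nrow(hits))[-1]) {
    for (j in which(keep[seq_len(i - 1)])) {
      if (hits$intensity[j] == hits$intensity[i] &&
          abs(hits$z[j] - hits$z[i]) <= h &&
          abs(hits$y[j] - hits$y[i]) <= h &&
          abs(hits$x[j] - hits$x[i]) <= h) keep[i] <- FALSE
    }
  }
  hits <- hits[keep, ]
  rownames(hits) <- NULL
  hits
}

# all-pairs Chebyshev colocalization check
brute_force_coloc <- function(mb, ref, h) {
  events <- 0L
  for (i in seq_len(nrow(mb))) {
    hit <- FALSE
    for (j in seq_len(nrow(ref))) {
      if (abs(mb$z[i] - ref$z[j]) <= h && abs(mb$y[i] - ref$y[j]) <= h &&
          abs(mb$x[i] - ref$x[j]) <= h) hit <- TRUE
    }
    if (hit) events <- events + 1L
  }
  list(n_coloc_events = events, percent = 100 * events / nrow(mb))
}

# all permutations of a vector
all_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  do.call(c, lapply(seq_along(v), function(i) {
    lapply(all_perms(v[-i]), function(p) c(v[i], p))
  }))
}

# exhaustive gated assignment between two point sets: minimizes
# sum of squared link distances + b * (number unmatched), b = (1.05 gate)^2;
# returns the optimal match vector (index into set 2 for each point of set 1)
brute_force_match <- function(x1, y1, x2, y2, gate) {
  n <- length(x1); m <- length(x2)
  b <- (1.05 * gate)^2
  best_cost <- Inf; best <- rep(NA_integer_, n)
  subsets1 <- unlist(lapply(0:min(n, m), function(k) {
    if (k == 0) list(integer(0)) else utils::combn(n, k, simplify = FALSE)
  }), recursive = FALSE)
  for (s1 in subsets1) {
    k <- length(s1)
    s2set <- if (k == 0) list(integer(0)) else utils::combn(m, k, simplify = FALSE)
    for (s2 in s2set) {
      for (p in all_perms(s2)) {
        d2 <- (x1[s1] - x2[p])^2 + (y1[s1] - y2[p])^2
        if (any(d2 > gate^2)) next
        cost <- sum(d2) + b * (n - k) + b * (m - k)
        if (cost < best_cost - 1e-12) {
          best_cost <- cost
          best <- rep(NA_integer_, n)
          best[s1] <- p
        }
      }
    }
  }
  list(match = best, cost = best_cost)
}

# greedy truth-to-detection matching within a radius; returns tp/fp/fn
match_detections <- function(truth, found, radius) {
  used <- rep(FALSE, nrow(found))
  tp <- 0L; fn <- 0L
  for (k in seq_len(nrow(truth))) {
    if (nrow(found)) {
      d <- sqrt((found$z - truth$z[k])^2 + (found$y - truth$y[k])^2 +
                  (found$x - truth$x[k])^2)
      j <- which(d <= radius & !used)
    } else j <- integer(0)
    if (length(j)) {
      used[j[which.min(d[j])]] <- TRUE
      tp <- tp + 1L
    } else fn <- fn + 1L
  }
  list(tp = tp, fn = fn, fp = sum(!used))
}
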
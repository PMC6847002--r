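render_simple_movie <- function(truth, rows = 64, cols = 64, amplitude = 300,
                                seed = 1, noiseless = FALSE) {
  n_frames <- max(truth$tracks$frame)
  p <- acquisition_params(
    image_shape = c(n_frames, rows, cols),
    frame_interval = truth$frame_interval,
    background_level = if (noiseless) 0 else 100,
    read_noise_sd = if (noiseless) 0 else 2)
  render_movie(truth, p, seed = seed, amplitude = amplitude,
               shot_noise = !noiseless)
}

test_that("the assignment solver matches exhaustive enumeration on random costs", {
  set.seed(41)
  for (rep in 1:30) {
    n <- sample(1:4, 1); m <- n + sample(0:2, 1)
    C <- matrix(stats::runif(n * m), n, m)
    sol <- spotloci:::.lap_solve(C)
    got <- sum(C[cbind(seq_len(n), sol)])
    best <- Inf
    for (cols in utils::combn(m, n, simplify = FALSE)) {
      for (p in all_perms(cols)) {
        best <- min(best, sum(C[cbind(seq_len(n), p)]))
      }
    }
    expect_equal(got, best)
  }
})

test_that("a blank movie yields no peaks", {
  mv <- time_lapse(array(100, c(5, 32, 32)), 0.1, 0.16)
  expect_equal(nrow(detect_peaks_2d(mv, sigma = 2, threshold = 1)), 0)
})

test_that("a stationary rendered spot is localized within 0.1 px each frame", {
  tr <- simulate_tracks(1, 8, 0.1, D = 0, v = 0, loc_noise_sd = 0, seed = 2,
                        extent = c(8, 8))
  mv <- render_simple_movie(tr, noiseless = TRUE)
  pk <- detect_peaks_2d(mv, sigma = 2, threshold = 1)
  expect_equal(nrow(pk), 8)
  truth <- tr$tracks[tr$tracks$particle == 1, ]
  expect_true(all(abs(pk$x - truth$x) < 0.1 * 0.16))
  expect_true(all(abs(pk$y - truth$y) < 0.1 * 0.16))
})

test_that("per-frame peak recall is at least 0.95 under realistic noise", {
  tr <- simulate_tracks(5, 40, 0.1, D = 0.005, v = 0, loc_noise_sd = 0,
                        seed = 3, extent = c(10, 10))
  mv <- render_simple_movie(tr, amplitude = 10 * sqrt(104), seed = 4)
  pk <- detect_peaks_2d(mv, sigma = 2)
  found <- 0L; total <- 0L
  for (f in 1:40) {
    tf <- tr$tracks[tr$tracks$frame == f, ]
    pf <- pk[pk$frame == f, ]
    total <- total + nrow(tf)
    for (i in seq_len(nrow(tf))) {
      if (nrow(pf) &&
          min(sqrt((pf$x - tf$x[i])^2 + (pf$y - tf$y[i])^2)) <= 0.16) {
        found <- found + 1L
      }
    }
  }
  expect_gte(found / total, 0.95)
})

test_that("single-particle and well-separated-pair linking are trivial and swap-free", {
  pk <- data.frame(frame = 1:10, x = 1 + 0.01 * (1:10), y = 2,
                   intensity = 1)
  tr <- link_frames(pk, 0.5)
  expect_equal(length(unique(tr$track_id)), 1)
  expect_equal(nrow(tr), 10)
  two <- rbind(
    data.frame(frame = 1:10, x = 1, y = 1 + 0.005 * (1:10), intensity = 1),
    data.frame(frame = 1:10, x = 5, y = 1, intensity = 1))
  tr2 <- link_frames(two, 0.5)
  expect_equal(length(unique(tr2$track_id)), 2)
  for (id in unique(tr2$track_id)) {
    expect_lt(stats::sd(tr2$x[tr2$track_id == id]), 1e-9)
  }
})

test_that("frame-to-frame linking equals the exhaustive gated assignment oracle", {
  set.seed(43)
  gate <- 0.5
  for (rep in 1:15) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    p1 <- data.frame(frame = 1, x = stats::runif(n1, 0, 2),
                     y = stats::runif(n1, 0, 2), intensity = 1)
    p2 <- data.frame(frame = 2, x = stats::runif(n2, 0, 2),
                     y = stats::runif(n2, 0, 2), intensity = 1)
    tr <- link_frames(rbind(p1, p2), gate)
    # recover the implied frame-1 -> frame-2 matching
    p1o <- p1[order(p1$x, p1$y), ]; p2o <- p2[order(p2$x, p2$y), ]
    match_got <- rep(NA_integer_, n1)
    for (id in unique(tr$track_id)) {
      seg <- tr[tr$track_id == id, ]
      if (nrow(seg) == 2) {
        i <- which(abs(p1o$x - seg$x[1]) < 1e-12 & abs(p1o$y - seg$y[1]) < 1e-12)
        j <- which(abs(p2o$x - seg$x[2]) < 1e-12 & abs(p2o$y - seg$y[2]) < 1e-12)
        match_got[i] <- j
      }
    }
    oracle <- brute_force_match(p1o$x, p1o$y, p2o$x, p2o$y, gate)
    cost_got <- sum((p1o$x - p2o$x[match_got])^2 +
                      (p1o$y - p2o$y[match_got])^2, na.rm = TRUE) +
      (1.05 * gate)^2 * (sum(is.na(match_got)) +
                           (n2 - sum(!is.na(match_got))))
    expect_equal(cost_got, oracle$cost, tolerance = 1e-10)
  }
})

test_that("linking is invariant to the ordering of the input peak table", {
  set.seed(44)
  pk <- do.call(rbind, lapply(1:6, function(f) {
    data.frame(frame = f, x = stats::runif(4, 0, 3),
               y = stats::runif(4, 0, 3), intensity = 1)
  }))
  t1 <- link_frames(pk, 0.8)
  t2 <- link_frames(pk[sample.int(nrow(pk)), ], 0.8)
  expect_equal(t1, t2)
})

test_that("gap closing with both gates zero is the identity", {
  pk <- data.frame(frame = 1:10, x = 0.01 * (1:10), y = 0, intensity = 1)
  tr <- link_frames(pk, 0.5)
  expect_identical(close_gaps(tr, 0, 0), tr)
})

test_that("a track interrupted for three frames is reassembled with its gap recorded", {
  pk <- data.frame(frame = 1:20, x = 0.02 * (1:20), y = 1, intensity = 1)
  pk <- pk[!(pk$frame %in% 10:12), ]
  tr <- link_frames(pk, 0.5)
  expect_equal(length(unique(tr$track_id)), 2)
  merged <- close_gaps(tr, 0.4, 4)
  expect_equal(length(unique(merged$track_id)), 1)
  expect_equal(track_gaps(merged), 10:12)
})

test_that("gap closing equals brute-force optimal end-start matching", {
  set.seed(46)
  gate <- 0.4; maxgap <- 4
  # six short tracks with random dropouts, well separated in space
  segs <- list()
  for (k in 1:6) {
    x0 <- k * 2; f0 <- sample(1:3, 1)
    frames <- f0:(f0 + 12)
    drop <- sample(5:9, sample(1:3, 1))
    frames <- setdiff(frames, drop)
    segs[[k]] <- data.frame(frame = frames, x = x0 + 0.01 * frames,
                            y = 1, intensity = 1)
  }
  pk <- do.call(rbind, segs)
  tr <- link_frames(pk, 0.5)
  expect_gt(length(unique(tr$track_id)), 6)  # dropouts fragmented the tracks
  merged <- close_gaps(tr, gate, maxgap)
  # particles sit 2 um apart (> gate), so the optimal matching must exactly
  # reassemble each particle's fragment chain: 6 tracks, each covering one
  # particle's full frame set and staying within its 2 um lane
  expect_equal(length(unique(merged$track_id)), 6)
  lanes <- sort(round(sapply(unique(merged$track_id), function(id) {
    min(merged$x[merged$track_id == id])
  })))
  expect_equal(lanes, (1:6) * 2)
  for (id in unique(merged$track_id)) {
    seg <- merged[merged$track_id == id, ]
    expect_lt(diff(range(seg$x)), 1)
    k <- round(min(seg$x) / 2)
    expect_setequal(seg$frame, segs[[k]]$frame)
  }
})

test_that("gap closing matches exhaustive matching enumeration on a small fragment set", {
  gate <- 0.4; maxgap <- 4
  # two particles, two fragments each, constructed so an end has several
  # feasible continuations and only optimal matching resolves them
  frag <- list(
    data.frame(frame = 1:4, x = 1.00 + 0.01 * (1:4), y = 1, intensity = 1),
    data.frame(frame = 7:10, x = 1.10 + 0.01 * (7:10), y = 1, intensity = 1),
    data.frame(frame = 1:5, x = 1.30 + 0.01 * (1:5), y = 1, intensity = 1),
    data.frame(frame = 8:10, x = 1.35 + 0.01 * (8:10), y = 1, intensity = 1))
  tr <- link_frames(do.call(rbind, frag), 0.05)
  ids <- sort(unique(tr$track_id))
  expect_equal(length(ids), 4)
  merged <- close_gaps(tr, gate, maxgap)
  # oracle: enumerate every one-to-one end-start matching
  ends <- t(sapply(ids, function(i) {
    s <- tr[tr$track_id == i, ]
    c(max(s$frame), s$x[which.max(s$frame)], s$y[which.max(s$frame)])
  }))
  starts <- t(sapply(ids, function(i) {
    s <- tr[tr$track_id == i, ]
    c(min(s$frame), s$x[which.min(s$frame)], s$y[which.min(s$frame)])
  }))
  b <- (1.05 * gate)^2
  n <- length(ids)
  best_cost <- Inf; best_pairs <- NULL
  choices <- expand.grid(rep(list(0:n), n))  # successor of each end (0 = none)
  for (r in seq_len(nrow(choices))) {
    succ <- as.integer(choices[r, ])
    nz <- succ[succ > 0]
    if (anyDuplicated(nz)) next
    cost <- 0; ok <- TRUE; npair <- 0L
    for (i in seq_len(n)) {
      j <- succ[i]
      if (j == 0) { cost <- cost + b; next }
      df <- starts[j, 1] - ends[i, 1]
      d2 <- (starts[j, 2] - ends[i, 2])^2 + (starts[j, 3] - ends[i, 3])^2
      if (j == i || df < 2 || df > maxgap + 1 || d2 > gate^2) { ok <- FALSE; break }
      cost <- cost + d2; npair <- npair + 1L
    }
    if (!ok) next
    cost <- cost + b * (n - npair)  # unmatched starts
    if (cost < best_cost - 1e-12) { best_cost <- cost; best_pairs <- succ }
  }
  n_merges_oracle <- sum(best_pairs > 0)
  expect_equal(length(unique(merged$track_id)), n - n_merges_oracle)
})

test_that("channel pairing is mutual-nearest-neighbor with gating", {
  tr <- do.call(rbind, lapply(1:4, function(k) {
    data.frame(track_id = k, frame = 1:10, x = k * 2 + 0.01 * (1:10), y = 1)
  }))
  p <- pair_channels(tr, tr, gate = 0.5)
  expect_equal(p$track_a, p$track_b)
  expect_equal(nrow(p), 4)
  far <- tr; far$x <- far$x + 5  # shifts every centroid past the gate
  expect_equal(nrow(pair_channels(tr, far, gate = 0.5)), 0)
  expect_warning(pair_channels(tr[0, ], tr), "empty")
})

test_that("pairing recovers the constructed correspondence in a shuffled scene", {
  set.seed(47)
  base <- lapply(1:4, function(k) {
    data.frame(frame = 1:20,
               x = k * 2 + cumsum(stats::rnorm(20, 0, 0.02)),
               y = 1 + cumsum(stats::rnorm(20, 0, 0.02)))
  })
  a <- do.call(rbind, lapply(1:4, function(k) {
    cbind(track_id = k, base[[k]])
  }))
  perm <- c(3, 1, 4, 2)
  b <- do.call(rbind, lapply(1:4, function(k) {
    df <- base[[perm[k]]]
    df$x <- df$x + 0.05  # small inter-channel offset
    cbind(track_id = k, df)
  }))
  p <- pair_channels(a, b, gate = 0.5)
  expect_equal(nrow(p), 4)
  expect_equal(perm[p$track_b], p$track_a)
})

test_that("no peak is in two tracks and all peaks are retained", {
  set.seed(48)
  pk <- do.call(rbind, lapply(1:8, function(f) {
    data.frame(frame = f, x = stats::runif(5, 0, 4),
               y = stats::runif(5, 0, 4), intensity = 1)
  }))
  tr <- link_frames(pk, 0.6)
  expect_equal(nrow(tr), nrow(pk))
  expect_equal(anyDuplicated(tr[, c("frame", "x", "y")]), 0)
})

test_that("tracking a rendered Brownian movie recovers most truth track length", {
  tr <- simulate_tracks(4, 30, 0.1, D = 0.004, v = 0, loc_noise_sd = 0,
                        seed = 49, extent = c(9, 9))
  mv <- render_simple_movie(tr, amplitude = 10 * sqrt(104), seed = 50)
  pk <- detect_peaks_2d(mv, sigma = 2)
  tracks <- filter_tracks(link_frames(pk, 0.5), 2)
  recovered <- 0
  for (p in 1:4) {
    truth <- tr$tracks[tr$tracks$particle == p, ]
    best <- 0
    for (id in unique(tracks$track_id)) {
      seg <- tracks[tracks$track_id == id, ]
      common <- intersect(seg$frame, truth$frame)
      if (length(common) < 2) next
      d <- sqrt((seg$x[match(common, seg$frame)] -
                   truth$x[match(common, truth$frame)])^2 +
                  (seg$y[match(common, seg$frame)] -
                     truth$y[match(common, truth$frame)])^2)
      if (mean(d) < 2 * 0.16) best <- max(best, length(common))
    }
    recovered <- recovered + best
  }
  expect_gte(recovered / (4 * 30), 0.9)
})
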
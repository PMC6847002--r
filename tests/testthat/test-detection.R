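as_stack <- function(m) image_stack(array(m, c(1, nrow(m), ncol(m))))

test_that("rolling ball removes flat background and preserves narrow peaks", {
  flat <- as_stack(matrix(100, 30, 30))
  expect_true(all(rolling_ball_subtract(flat, 2)$voxels == 0))
  imp <- matrix(0, 30, 30); imp[15, 15] <- 500
  out <- rolling_ball_subtract(as_stack(imp), 2)
  expect_gt(out$voxels[1, 15, 15], 0.99 * 500)
  expect_error(rolling_ball_subtract(flat, 0), "radius")
})

test_that("rolling ball recovers a Gaussian spot sitting on a linear ramp", {
  A <- 100
  spot <- outer(1:41, 1:41,
                function(y, x) A * exp(-((y - 21)^2 + (x - 21)^2) / (2 * 2^2)))
  ramp <- outer(1:41, 1:41, function(y, x) 2 * x + 50)
  out <- rolling_ball_subtract(as_stack(spot + ramp), 6)
  expect_lt(abs(out$voxels[1, 21, 21] - A) / A, 0.10)
})

test_that("LoG filter is zero on constants and peaks at matched blob centers", {
  p <- acquisition_params(image_shape = c(11, 31, 31), background_level = 0,
                          read_noise_sd = 0)
  const <- image_stack(array(70, c(11, 31, 31)))
  expect_lt(max(abs(log_filter_3d(const, 2, 1)$voxels)), 1e-9)
  spot <- spotloci:::.render_spots_3d(c(11, 31, 31),
                                      matrix(c(6, 16, 16), 1), 100, 2, 1)
  resp <- log_filter_3d(image_stack(spot), 2, 1)$voxels
  expect_equal(arrayInd(which.max(resp), dim(resp)), matrix(c(6L, 16L, 16L), 1))
})

test_that("at a fixed filter scale the narrower of two blobs responds more", {
  shape <- c(13, 61, 61)
  narrow <- spotloci:::.render_spots_3d(shape, matrix(c(7, 15, 15), 1), 100, 2, 1)
  wide <- spotloci:::.render_spots_3d(shape, matrix(c(7, 45, 45), 1), 100, 4, 4)
  resp <- log_filter_3d(image_stack(narrow + wide), 2, 1)$voxels
  expect_gt(resp[7, 15, 15], resp[7, 45, 45])
})

test_that("stacks with fewer than 3 slices fall back to 2D LoG with a warning", {
  m <- matrix(0, 21, 21); m[11, 11] <- 100
  thin <- image_stack(array(rep(m, 2), c(21, 21, 2)))
  thin <- image_stack(aperm(array(rep(m, 2), c(21, 21, 2)), c(3, 1, 2)))
  expect_warning(resp <- log_filter_3d(thin, 2, 1), "2D")
  expect_equal(arrayInd(which.max(resp$voxels), dim(resp$voxels))[2:3],
               c(11L, 11L))
})

test_that("slice maxima match an exhaustive 8-neighbor scan on random impulses", {
  set.seed(31)
  m <- matrix(0, 40, 40)
  pts <- matrix(numeric(0), ncol = 2)
  while (nrow(pts) < 20) {  # sequentially place isolated impulses
    cand <- c(sample(5:36, 1), sample(5:36, 1))
    if (nrow(pts) == 0 ||
        min(abs(pts[, 1] - cand[1]) + abs(pts[, 2] - cand[2])) >= 3) {
      pts <- rbind(pts, cand)
    }
  }
  vals <- c(stats::runif(15, 50, 100), stats::runif(5, 1, 9))
  m[pts] <- vals
  st <- as_stack(m)
  got <- find_slice_maxima(st, threshold = 10)
  expect_equal(nrow(got), 15)
  oracle <- brute_force_3d_maxima(st$voxels, threshold = 10, h = 0)
  expect_equal(got[, c("row", "col", "intensity")],
               oracle[, c("y", "x", "intensity")],
               ignore_attr = TRUE)
  # all-zero slice yields nothing; single impulse yields exactly itself
  expect_equal(nrow(find_slice_maxima(as_stack(matrix(0, 10, 10)),
                                      threshold = 0)), 0)
  one <- matrix(0, 10, 10); one[4, 7] <- 5
  got1 <- find_slice_maxima(as_stack(one), threshold = 1)
  expect_equal(got1[, c("row", "col")], data.frame(row = 4L, col = 7L),
               ignore_attr = TRUE)
})

test_that("equal-intensity plateaus contribute one representative, first in scan order", {
  m <- matrix(0, 12, 12)
  m[5, 5] <- 7; m[5, 6] <- 7  # 2-pixel plateau
  got <- find_slice_maxima(as_stack(m), threshold = 1)
  expect_equal(nrow(got), 1)
  expect_equal(c(got$row, got$col), c(5, 5))
})

test_that("the cube rule keeps exactly one locus per isolated 3D spot", {
  shape <- c(12, 40, 40)
  spot <- spotloci:::.render_spots_3d(shape, matrix(c(6.2, 20.4, 23.1), 1),
                                      100, 1, 1)
  st <- image_stack(spot)
  mx <- find_slice_maxima(st, threshold = 1)
  expect_gt(nrow(mx), 1)  # the spot is a 2D maximum in several slices
  loci <- select_3d_maxima(mx, st)
  expect_equal(nrow(loci), 1)
  expect_equal(c(loci$z, loci$y, loci$x), c(6, 20, 23))
})

test_that("the cube rule agrees with brute force on many random spots", {
  set.seed(77)
  shape <- c(14, 48, 48)
  n <- 30
  pos <- matrix(numeric(0), ncol = 3)
  while (nrow(pos) < n) {  # sequential placement, pairwise separation >= 6
    cand <- c(stats::runif(1, 3, 12), stats::runif(1, 4, 45),
              stats::runif(1, 4, 45))
    if (nrow(pos) == 0 ||
        min(sqrt(rowSums(sweep(pos, 2, cand)^2))) >= 6) {
      pos <- rbind(pos, cand)
    }
  }
  v <- spotloci:::.render_spots_3d(shape, pos, stats::runif(n, 50, 150), 1, 1)
  st <- image_stack(v)
  mx <- find_slice_maxima(st, threshold = 5)
  got <- select_3d_maxima(mx, st, cube_halfwidth = 2)
  oracle <- brute_force_3d_maxima(st$voxels, threshold = 5, h = 2)
  expect_equal(got, oracle, ignore_attr = TRUE)
})

test_that("raising the threshold never increases the number of loci", {
  p <- acquisition_params(image_shape = c(12, 40, 40))
  g <- generate_stack(p, 5, seed = 9)
  filt <- log_filter_3d(rolling_ball_subtract(g$stack, 2), 2, 1)
  thresholds <- c(0, 1, 2, 5, 10, 20)
  n <- sapply(thresholds, function(th) {
    nrow(select_3d_maxima(find_slice_maxima(filt, threshold = th), filt))
  })
  expect_true(all(diff(n) <= 0))
})

test_that("every 3D locus is also a per-slice 2D maximum (set inclusion)", {
  p <- acquisition_params(image_shape = c(12, 40, 40))
  g <- generate_stack(p, 4, seed = 17)
  filt <- log_filter_3d(rolling_ball_subtract(g$stack, 2), 2, 1)
  mx <- find_slice_maxima(filt, threshold = 2)
  loci <- select_3d_maxima(mx, filt)
  key <- function(a, b, c) paste(a, b, c)
  expect_true(all(key(loci$z, loci$y, loci$x) %in%
                    key(mx$slice, mx$row, mx$col)))
})

test_that("per-nucleus counts reproduce the constructed truth", {
  # three nuclei side by side in one field, noiseless
  labels <- matrix(0L, 40, 120)
  masks <- list()
  for (k in 1:3) {
    sub <- make_nucleus_mask(40, 40)
    block <- matrix(0L, 40, 120)
    block[, (k - 1) * 40 + 1:40] <- sub * k
    labels <- labels + block
  }
  p <- acquisition_params(image_shape = c(10, 40, 120), background_level = 10,
                          read_noise_sd = 0)
  truth_counts <- c(2, 5, 1)
  pos <- rbind(
    c(4.2, 15.3, 14.6), c(6.8, 24.1, 25.2),                  # nucleus 1
    c(3.9, 14.2, 54.8), c(5.5, 26.3, 55.1), c(7.1, 20.0, 63.7),
    c(4.4, 27.6, 66.9), c(6.2, 13.5, 64.2),                  # nucleus 2
    c(5.0, 20.5, 100.4))                                     # nucleus 3
  v <- 10 + spotloci:::.render_spots_3d(c(10, 40, 120), pos,
                                        rep(200, nrow(pos)), 1, 1)
  st <- image_stack(round(v))
  loci <- detect_loci(st)
  counts <- count_loci(loci, labels)
  expect_equal(counts$n_loci, truth_counts)
  # nuclei with no loci report zero
  empty <- detect_loci(image_stack(array(10, c(10, 40, 120))))
  expect_equal(count_loci(empty, labels)$n_loci, c(0, 0, 0))
  # a locus outside every ROI is an assignment error
  fake <- data.frame(z = 1, y = 1, x = 1, intensity = 1)
  expect_error(count_loci(fake, labels), "outside all ROIs")
})

test_that("noiseless well-separated scenes are detected with recall and precision 1", {
  p <- acquisition_params(image_shape = c(12, 48, 48), background_level = 50,
                          read_noise_sd = 0)
  tp <- 0L; fp <- 0L; fn <- 0L
  for (i in 1:5) {
    g <- generate_stack(p, 5, seed = 300 + i, shot_noise = FALSE,
                        min_separation = 8)
    loci <- detect_loci(g$stack, roi = nucleus_roi(g$truth$nucleus_mask))
    m <- match_detections(g$truth$positions, loci, radius = 2)
    tp <- tp + m$tp; fp <- fp + m$fp; fn <- fn + m$fn
  }
  expect_equal(fn, 0L)
  expect_equal(fp, 0L)
})

test_that("detection recall under realistic noise is at least 0.95 across seeds", {
  p <- acquisition_params(image_shape = c(12, 48, 48))
  sd_bg <- sqrt(p$background_level + p$read_noise_sd^2)
  tp <- 0L; fn <- 0L
  for (i in 1:25) {
    g <- generate_stack(p, 4, amplitude_range = c(10 * sd_bg, 12 * sd_bg),
                        seed = 500 + i)
    loci <- detect_loci(g$stack, roi = nucleus_roi(g$truth$nucleus_mask))
    m <- match_detections(g$truth$positions, loci, radius = 2)
    tp <- tp + m$tp; fn <- fn + m$fn
  }
  expect_gte(tp / (tp + fn), 0.95)
})
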
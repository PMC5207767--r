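test_that("detection parameter validation and channel presets", {
  expect_equal(default_threshold("Cy3"), 170) # midpoint of 150-190
  expect_equal(default_threshold("Cy5"), 140) # midpoint of 130-150
  expect_error(detection_params(intensity_threshold = 0), "> 0")
  expect_error(detection_params(aoi_size = 6), "odd")
  expect_error(detection_params(area_min = 10, area_max = 2), "<=")
})

test_that("an all-zero frame yields no detections", {
  out <- detect_spots(matrix(0, 32, 32), detection_params(170))
  expect_equal(nrow(out), 0)
  expect_error(detect_spots(array(0, c(3, 3, 3))), "matrix")
})

test_that("well-separated spots are recovered with high precision and recall", {
  cam <- camera_model()
  params <- detection_params(170)
  hits <- 0; truths <- 0; dets <- 0
  for (s in 1:50) {
    set.seed(s)
    # 20 spots on a grid jittered to stay >= 10 px apart, SNR >= 5
    centers <- expand.grid(row = seq(12, 116, by = 26), col = seq(12, 116, by = 26))
    centers <- centers[sample(nrow(centers), 20), ]
    centers$row <- centers$row + runif(20, -3, 3)
    centers$col <- centers$col + runif(20, -3, 3)
    spots <- tibble::tibble(
      spot_id = 1:20, channel = "Cy3", row = centers$row, col = centers$col,
      n_fluorophores = 1L,
      bleach_frames = replicate(20, 1000L, simplify = FALSE),
      unit_intensity = 3000
    )
    field <- manual_spot_field(spots, dim = c(128, 128), n_frames = 1)
    st <- render_movie(field, cam, "Cy3", seed = 1000 + s)
    sub <- subtract_stack(st, radius = 50)
    det <- detect_spots(get_frame(sub, 0), params)
    matched <- vapply(1:20, function(i) {
      any((det$row - spots$row[i])^2 + (det$col - spots$col[i])^2 <= 4)
    }, logical(1))
    hits <- hits + sum(matched)
    truths <- truths + 20
    dets <- dets + nrow(det)
  }
  expect_gte(hits / truths, 0.95) # recall
  expect_gte(hits / dets, 0.95)   # precision (every detection near a truth)
})

test_that("raising the threshold never increases the spot count", {
  cam <- camera_model()
  spec <- condition_spec("encoded")
  thresholds <- seq(120, 400, by = 40)
  for (s in 1:5) {
    field <- simulate_spot_field(spec, c(96, 96), 0.2, n_frames = 1, seed = s)
    st <- render_movie(field, cam, "Cy3", seed = 100 + s)
    f0 <- get_frame(subtract_stack(st, radius = 50), 0)
    counts <- vapply(thresholds, function(thr) {
      # area_max unbounded: an area ceiling can gate a merged blob back in
      # as it shrinks, which is orthogonal to threshold monotonicity
      count_spots(f0, detection_params(thr, area_max = 1e9))
    }, numeric(1))
    expect_true(all(diff(counts) <= 0))
  }
  # AOI counts share the property when spots are resolvable: the dedup and
  # window-clip stages depend on centroids, which jitter for blended spots
  set.seed(61)
  f <- matrix(0, 96, 96)
  centers <- expand.grid(row = seq(10, 90, by = 16), col = seq(10, 90, by = 16))
  for (i in seq_len(nrow(centers))) {
    f[centers$row[i] + (-1:1), centers$col[i] + (-1:1)] <- runif(1, 150, 600)
  }
  counts <- vapply(thresholds, function(thr) {
    nrow(detect_spots(f, detection_params(thr)))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_gt(counts[1], counts[length(counts)])
})

test_that("detection is translation-equivariant for interior spots", {
  set.seed(8)
  f <- matrix(0, 64, 64)
  for (k in 1:4) {
    r <- c(15, 15, 40, 45)[k]; c <- c(15, 40, 22, 50)[k]
    f[r + (-1:1), c + (-1:1)] <- 400 + 50 * k
  }
  base <- detect_spots(f, detection_params(200))
  g <- matrix(0, 64, 64)
  g[4:64, 6:64] <- f[1:61, 1:59] # shift by (+3, +5)
  shifted <- detect_spots(g, detection_params(200))
  expect_equal(shifted$row, base$row + 3)
  expect_equal(shifted$col, base$col + 5)
})

test_that("AOIs are deduplicated, window-clipped and deterministically ordered", {
  f <- matrix(0, 32, 32)
  f[10:11, 10:11] <- 500           # spot A ...
  f[12:13, 12:13] <- 600           # ... touches spot B: merged, B kept
  f[20:21, 6:7] <- 500             # interior spot, window fits
  f[5:6, 30:31] <- 500             # 7x7 window exits the right edge
  det <- detect_spots(f, detection_params(100, min_separation = 4))
  # A+B collapse to one AOI, right-edge spot clipped out
  expect_equal(nrow(det), 2)
  expect_true(all(det$col + 3 <= 31))
  expect_equal(det, det[order(det$row, det$col), ])
})

test_that("spot density arithmetic and validation", {
  expect_equal(spot_density(0, c(100, 100), 0.2), 0)
  # 140 AOIs on a 1000 um^2 field -> 0.14 spots/um^2
  expect_equal(spot_density(140, c(250, 100), 0.2), 0.14)
  expect_error(spot_density(10, c(0, 100), 0.2), "positive")
  expect_error(spot_density(10, c(10, 10), 0), "positive")
})

test_that("density estimate is unbiased and halves its variance when area doubles", {
  spec <- condition_spec("encoded")
  dens <- function(side, seeds) {
    vapply(seeds, function(s) {
      n <- nrow(simulate_spot_field(spec, c(side, side), 0.2, seed = s)$cy3)
      spot_density(n, c(side, side), 0.2)
    }, numeric(1))
  }
  d1 <- dens(100, 1:150)
  d2 <- dens(142, 151:300) # ~double the area
  expect_lt(abs(mean(d1) - 0.14), 3 * sd(d1) / sqrt(150))
  expect_lt(abs(mean(d2) - 0.14), 3 * sd(d2) / sqrt(150))
  expect_gt(var(d1) / var(d2), 1.4)
  expect_lt(var(d1) / var(d2), 2.9)
})

test_that("overlap-corrected density de-biases resolution-limited counts", {
  # zero observed -> zero; correction grows with count and stays above raw
  expect_equal(density_estimate(0, c(128, 128), 0.2), 0)
  raw <- spot_density(80, c(128, 128), 0.2)
  expect_gt(density_estimate(80, c(128, 128), 0.2), raw)
  # for a small count the correction is negligible
  expect_equal(density_estimate(2, c(128, 128), 0.2),
    spot_density(2, c(128, 128), 0.2),
    tolerance = 1e-2
  )
})

test_that("density summary pools per-oocyte means", {
  d <- tibble::tibble(
    oocyte = c(1, 1, 2), movie = c(1, 2, 1),
    density = c(0.10, 0.20, 0.30)
  )
  s <- density_summary(d)
  expect_equal(s$mean, mean(c(0.15, 0.30)))
  expect_equal(s$n_oocytes, 2)
})
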
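test_that("condition presets carry the reported study densities", {
  enc <- condition_spec("encoded")
  expect_equal(enc$density_cy3, 0.14)
  expect_equal(enc$density_cy5, 0.08)
  mok <- condition_spec("mock")
  expect_equal(mok$density_cy3, 0.03)
  expect_equal(mok$density_cy5, 0.02)
  # mock bleaching is dominated by single-fluorophore spots
  expect_gte(mok$fluor_count_distribution[1], 0.8)
  expect_equal(sum(enc$fluor_count_distribution), 1)
})

test_that("invalid condition parameters are rejected", {
  expect_error(condition_spec("encoded", density_cy3 = -1), "densities")
  expect_error(
    condition_spec("encoded", fluor_count_distribution = c(0.5, 0.2)),
    "probability"
  )
  expect_error(
    condition_spec("encoded", colocalized_fraction = 1.5),
    "\\[0, 1\\]"
  )
  expect_error(
    condition_spec("encoded", registration_offset = c(5, 0)),
    "3 px"
  )
  expect_error(
    simulate_spot_field(condition_spec("encoded"), dim = c(0, 10)),
    "positive"
  )
})

test_that("zero density gives an empty spot field", {
  spec <- condition_spec("mock", density_cy3 = 0, density_cy5 = 0)
  f <- simulate_spot_field(spec, c(64, 64), 0.2, seed = 1)
  expect_equal(nrow(f$cy3), 0)
  expect_equal(nrow(f$cy5), 0)
  expect_equal(nrow(f$pairs), 0)
})

test_that("spot counts follow the Poisson law of the requested density", {
  # 0.14 spots/um^2 over 1000 um^2 -> Poisson(140); 200 seeds
  spec <- condition_spec("encoded")
  side <- round(sqrt(1000) / 0.2) # ~1000 um^2 at 0.2 um/px
  counts <- vapply(1:200, function(s) {
    nrow(simulate_spot_field(spec, c(side, side), 0.2, seed = s)$cy3)
  }, numeric(1))
  mu <- spec$density_cy3 * side^2 * 0.2^2
  expect_lt(abs(mean(counts) - mu), 3 * sqrt(mu / 200))
  expect_gt(var(counts) / mu, 0.7)
  expect_lt(var(counts) / mu, 1.3)
  # chi-square goodness of fit against Poisson(mu)
  qs <- unique(qpois(seq(0.1, 0.9, by = 0.1), mu))
  breaks <- c(-Inf, qs, Inf)
  obs <- table(cut(counts, breaks))
  expe <- diff(ppois(c(-Inf, qs, Inf), mu)) * 200
  chi2 <- sum((as.numeric(obs) - expe)^2 / expe)
  expect_gt(pchisq(chi2, length(expe) - 1, lower.tail = FALSE), 0.01)
})

test_that("ground-truth colocalized fraction converges to the spec value", {
  spec <- condition_spec("encoded",
    density_cy3 = 0.3, density_cy5 = 0.6,
    colocalized_fraction = 0.3
  )
  n5 <- 0; npair <- 0
  for (s in 1:5) {
    f <- simulate_spot_field(spec, c(158, 158), 0.2, seed = s)
    n5 <- n5 + nrow(f$cy5)
    npair <- npair + nrow(f$pairs)
  }
  expect_gte(n5, 500)
  se <- sqrt(0.3 * 0.7 / n5)
  expect_lt(abs(npair / n5 - 0.3), 3 * se + 0.01) # small out-of-frame loss
})

test_that("bleach traces are exact staircases plus the requested noise", {
  z <- simulate_bleach_trace(0, 3000, integer(0), n_frames = 20)
  expect_equal(z$trace$intensity, rep(0, 20))
  expect_equal(length(z$true_steps), 0)

  one <- simulate_bleach_trace(1, 3000, 10L, n_frames = 30, noise_sd = 0)
  expect_equal(unique(diff(one$trace$intensity)), c(0, -3000))
  expect_equal(one$true_steps, 10L)
  expect_equal(one$trace$intensity[11:30], rep(0, 20))

  five <- simulate_bleach_trace(5, 1000, c(3L, 7L, 12L, 20L, 33L),
    n_frames = 40, noise_sd = 0
  )
  d <- diff(five$trace$intensity)
  expect_equal(sum(d < 0), 5)
  expect_equal(five$trace$intensity[34:40], rep(0, 7))
  expect_error(simulate_bleach_trace(1, 3000, 5L, 10, noise_sd = -1), ">= 0")
  expect_error(simulate_bleach_trace(1, 3000, 5L, n_frames = 0), ">= 1")
})

test_that("noise-free rendering reproduces the background exactly and conserves PSF mass", {
  cam <- camera_model(
    psf_sigma = 1.5, background_offset = 200,
    background_gradient = c(0.5, -0.2), read_noise_sd = 0
  )
  f0 <- manual_spot_field(NULL, dim = c(40, 40), n_frames = 3)
  st <- render_movie(f0, cam, "Cy3", noise = FALSE)
  bg <- cymage:::background_plane(40, 40, cam)
  for (t in 0:2) expect_equal(get_frame(st, t), round(bg))

  # single interior spot, no background: frame sum = n x unit_intensity
  cam0 <- camera_model(
    psf_sigma = 1.5, background_offset = 0,
    background_gradient = c(0, 0), read_noise_sd = 0
  )
  f1 <- manual_spot_field(
    spot_row(20, 20, n = 2, bleach = list(c(1000L, 1000L)), unit = 5000),
    dim = c(40, 40), n_frames = 2
  )
  st1 <- render_movie(f1, cam0, "Cy3", noise = FALSE)
  expect_lt(abs(sum(get_frame(st1, 0)) - 10000) / 10000, 0.01)

  expect_error(
    render_movie(f1, camera_model(psf_sigma = 50), "Cy3"),
    "smaller"
  )
})

test_that("rendering is bit-identical under a fixed seed", {
  spec <- condition_spec("encoded")
  f <- simulate_spot_field(spec, c(48, 48), 0.2, n_frames = 5, seed = 9)
  a <- render_movie(f, camera_model(), "Cy3", seed = 33)
  b <- render_movie(f, camera_model(), "Cy3", seed = 33)
  expect_identical(unclass(a), unclass(b))
})

test_that("per-trace step count equals the number of fluorophores by construction", {
  spec <- condition_spec("encoded")
  f <- simulate_spot_field(spec, c(96, 96), 0.2, n_frames = 1e6, seed = 4)
  with_steps <- vapply(seq_len(nrow(f$cy3)), function(i) {
    length(f$cy3$bleach_frames[[i]])
  }, numeric(1))
  expect_equal(with_steps, as.numeric(f$cy3$n_fluorophores))
})

test_that("condition datasets round-trip through disk and are seed-reproducible", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  spec <- condition_spec("encoded")
  cam <- camera_model()
  d1 <- make_condition_dataset(spec, cam,
    dim = c(48, 48), n_frames = 5,
    out_dir = file.path(dir1, "enc"), seed = 7
  )
  d2 <- make_condition_dataset(spec, cam,
    dim = c(48, 48), n_frames = 5,
    out_dir = file.path(dir2, "enc"), seed = 7
  )
  for (p in c("cy3", "cy5", "spots", "pairs")) {
    expect_identical(
      readBin(d1$paths[[p]], "raw", file.size(d1$paths[[p]])),
      readBin(d2$paths[[p]], "raw", file.size(d2$paths[[p]]))
    )
  }
  st <- read_stack(d1$paths$cy3, pixel_size = 0.2, channel = "Cy3")
  expect_equal(n_frames(st), 5)
  expect_equal(frame_dim(st), c(48, 48))
  spots <- utils::read.csv(d1$paths$spots)
  expect_equal(nrow(spots), nrow(d1$field$cy3) + nrow(d1$field$cy5))
  meta <- jsonlite::read_json(d1$paths$metadata)
  expect_equal(meta$condition, "encoded")
  expect_equal(meta$density_cy3, 0.14)
  expect_equal(meta$density_cy5, 0.08)
})
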
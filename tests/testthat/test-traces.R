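test_that("trace extraction integrates the fixed AOI window", {
  st <- image_stack(array(3, c(4, 16, 16)))
  v <- extract_trace(st, 8, 8, aoi_size = 7)
  expect_equal(v, rep(3 * 49, 4))
  expect_equal(length(v), n_frames(st))
  expect_error(extract_trace(st, 1, 8), "leaves the frame")
})

test_that("a rendered single-fluorophore trace follows the truth exactly without noise", {
  cam <- camera_model(
    psf_sigma = 1.2, background_offset = 0,
    background_gradient = c(0, 0), read_noise_sd = 0
  )
  spots <- spot_row(20, 20, n = 1, bleach = list(6L), unit = 3000)
  field <- manual_spot_field(spots, dim = c(41, 41), n_frames = 12)
  st <- render_movie(field, cam, "Cy3", noise = FALSE)
  v <- extract_trace(st, 20, 20)
  mass <- sum(cymage:::psf_patch(20, 20, 17:23, 17:23, 1.2))
  expect_equal(v[1:6], rep(3000 * mass, 6), tolerance = 1e-3)
  expect_equal(v[7:12], rep(0, 6))
})

test_that("noiseless staircases are recovered exactly", {
  set.seed(71)
  for (k in 1:6) {
    for (rep in 1:5) {
      T <- 60
      cf <- sort(sample(seq(4, T - 4, by = 3), k))
      drops <- runif(k, 0.5, 2)
      v <- make_staircase(T, cf, drops)
      fit <- count_bleach_steps(v, noise_sd = 0)
      expect_equal(fit$n_steps, k)
      expect_equal(fit$change_frames, cf)
      expect_true(fit$accepted)
    }
  }
})

test_that("an upward-only ramp yields no accepted steps", {
  v <- seq(0, 100, length.out = 50)
  fit <- count_bleach_steps(v)
  expect_false(fit$accepted)
  expect_equal(fit$rejection_reason, "upward_step")
})

test_that("single downward steps at SNR 3 are scored as one step", {
  set.seed(1234)
  ok <- 0
  for (i in 1:1000) {
    cf <- sample(20:80, 1)
    v <- make_staircase(100, cf, 3) + rnorm(100, 0, 1)
    fit <- count_bleach_steps(v)
    if (fit$n_steps == 1) ok <- ok + 1
  }
  expect_gte(ok / 1000, 0.90)
})

test_that("greedy fitting matches the exhaustive oracle on short traces", {
  set.seed(555)
  for (i in 1:200) {
    T <- sample(12:30, 1)
    k <- sample(0:2, 1)
    cf <- sort(sample(seq(3, T - 3), k))
    while (k == 2 && diff(cf) < 3) cf <- sort(sample(seq(3, T - 3), 2))
    drops <- runif(k, 5, 12)
    v <- make_staircase(T, cf, drops) + rnorm(T, 0, 1)
    fit <- count_bleach_steps(v, noise_sd = 1)
    expect_equal(
      fit$change_frames,
      oracle_steps(v, sigma = 1, kmax = max(3, fit$n_steps + 1))
    )
  }
})

test_that("incompletely bleached traces are rejected", {
  set.seed(2)
  # one step down but the trace plateaus well above baseline
  v <- make_staircase(80, 30, 10) + 10 + rnorm(80, 0, 1)
  fit <- count_bleach_steps(v, noise_sd = 1)
  expect_false(fit$accepted)
  expect_equal(fit$rejection_reason, "never_bleached")
  expect_error(count_bleach_steps(rep(NA_real_, 10)), "NA")
  expect_error(count_bleach_steps(1:3), "at least 5")
})

test_that("step fits tidy into segments and glance into summaries", {
  v <- make_staircase(30, c(10, 20), c(4, 4))
  fit <- count_bleach_steps(v, noise_sd = 0)
  td <- tidy(fit)
  expect_equal(nrow(td), 3)
  expect_equal(td$start_frame, c(0, 10, 20))
  expect_equal(td$end_frame, c(9, 19, 29))
  expect_equal(td$level, c(8, 4, 0))
  gl <- glance(fit)
  expect_true(gl$accepted)
  expect_equal(gl$n_steps, 2)
})

test_that("histograms pool counts per movie and relative frequencies per oocyte", {
  fits <- tibble::tibble(
    oocyte = 1, movie = 1, n_steps = c(1, 1, 2), accepted = TRUE
  )
  h <- aggregate_step_histogram(fits)
  expect_equal(h$absolute$count, c(2, 1))
  expect_equal(h$per_movie$rel, c(2 / 3, 1 / 3))
  expect_equal(h$n_traces, 3)

  # two oocytes with 1-step frequencies 0.4 and 0.6 pool to 0.5
  fits2 <- tibble::tibble(
    oocyte = rep(1:2, each = 5),
    movie = 1,
    n_steps = c(1, 1, 2, 2, 2, 1, 1, 1, 2, 2),
    accepted = TRUE
  )
  h2 <- aggregate_step_histogram(fits2)
  expect_equal(h2$pooled$mean[h2$pooled$n_steps == 1], 0.5)
  expect_equal(h2$pooled$sem[h2$pooled$n_steps == 1],
    sd(c(0.4, 0.6)) / sqrt(2))
  expect_error(
    aggregate_step_histogram(fits[0, ]),
    "no accepted traces"
  )
})

test_that("histogram counts are conserved over accepted traces", {
  set.seed(31)
  fits <- tibble::tibble(
    oocyte = sample(1:3, 200, TRUE), movie = sample(1:2, 200, TRUE),
    n_steps = sample(1:5, 200, TRUE), accepted = runif(200) < 0.8
  )
  h <- aggregate_step_histogram(fits)
  expect_equal(sum(h$absolute$count), sum(fits$accepted))
  rel_sums <- h$per_movie |>
    dplyr::group_by(oocyte, movie) |>
    dplyr::summarise(s = sum(rel), .groups = "drop")
  expect_equal(rel_sums$s, rep(1, nrow(rel_sums)))
})

test_that("step-distribution comparison is symmetric and null on identical data", {
  fits <- tibble::tibble(
    oocyte = rep(1:3, each = 4), movie = 1,
    n_steps = rep(c(1, 1, 2, 3), 3), accepted = TRUE
  )
  h <- aggregate_step_histogram(fits)
  cmp <- compare_step_distributions(h, h)
  expect_true(all(cmp$t == 0))
  expect_true(all(cmp$p == 1))

  fits_b <- tibble::tibble(
    oocyte = rep(1:3, each = 4), movie = 1,
    n_steps = rep(c(1, 2, 2, 3), 3), accepted = TRUE
  )
  fits_b$n_steps[1] <- 2
  hb <- aggregate_step_histogram(fits_b)
  ab <- compare_step_distributions(h, hb)
  ba <- compare_step_distributions(hb, h)
  expect_equal(ab$t, -ba$t)
  expect_equal(ab$p, ba$p)
  one <- aggregate_step_histogram(fits[fits$oocyte == 1, ])
  expect_error(compare_step_distributions(h, one), "2 oocytes")
})
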
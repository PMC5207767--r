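# Brute-force grayscale morphology oracle (direct definition, O(H W K));
# independent of the compiled implementation.
oracle_erode <- function(img, el) {
  H <- nrow(img); W <- ncol(img)
  out <- img * 0
  for (i in 1:H) {
    for (j in 1:W) {
      v <- Inf
      for (k in seq_along(el$dr)) {
        ii <- i + el$dr[k]; jj <- j + el$dc[k]
        if (ii >= 1 && ii <= H && jj >= 1 && jj <= W) {
          v <- min(v, img[ii, jj] - el$height[k])
        }
      }
      out[i, j] <- v
    }
  }
  out
}

oracle_dilate <- function(img, el) {
  H <- nrow(img); W <- ncol(img)
  out <- img * 0
  for (i in 1:H) {
    for (j in 1:W) {
      v <- -Inf
      for (k in seq_along(el$dr)) {
        ii <- i - el$dr[k]; jj <- j - el$dc[k]
        if (ii >= 1 && ii <= H && jj >= 1 && jj <= W) {
          v <- max(v, img[ii, jj] + el$height[k])
        }
      }
      out[i, j] <- v
    }
  }
  out
}

oracle_opening <- function(img, el) oracle_dilate(oracle_erode(img, el), el)

# Exhaustive change-point search minimizing the same penalized cost
# (SSE + k * lambda * sigma^2 * log T) with the same amplitude gate as the
# greedy fitter, over every changepoint set of size 0..kmax. Prefix sums
# make each candidate O(k); feasible for short traces only.
oracle_steps <- function(v, sigma, lambda = 3, min_step_snr = 2, kmax = 3) {
  T <- length(v)
  pen <- lambda * sigma^2 * log(T)
  s1 <- c(0, cumsum(v))
  s2 <- c(0, cumsum(v^2))
  cost_and_gate <- function(cps) {
    b <- c(0, cps, T)
    n <- diff(b)
    sums <- s1[b[-1] + 1] - s1[b[-length(b)] + 1]
    sqs <- s2[b[-1] + 1] - s2[b[-length(b)] + 1]
    means <- sums / n
    list(
      sse = sum(sqs - sums^2 / n),
      ok = all(abs(diff(means)) >= min_step_snr * sigma)
    )
  }
  best <- list(cps = integer(0), cost = cost_and_gate(integer(0))$sse)
  for (k in seq_len(min(kmax, T - 1))) {
    combs <- utils::combn(T - 1, k)
    for (ci in seq_len(ncol(combs))) {
      cand <- combs[, ci]
      cg <- cost_and_gate(cand)
      if (!cg$ok) next
      cost <- cg$sse + k * pen
      if (cost < best$cost - 1e-12) best <- list(cps = cand, cost = cost)
    }
  }
  as.integer(best$cps)
}

# Noiseless staircase trace descending to 0 through the given change frames
# (0-based) with the given per-step drops.
make_staircase <- function(T, change_frames, drops) {
  levels <- rev(cumsum(rev(c(drops, 0))))
  v <- numeric(T)
  b <- c(0, change_frames, T)
  for (i in seq_along(levels)) v[(b[i] + 1):b[i + 1]] <- levels[i]
  v
}

# Minimal hand-built spot field for rendering tests.
manual_spot_field <- function(spots, dim = c(64, 64), pixel_size = 0.2,
                              n_frames = 10, frame_interval = 1) {
  empty <- tibble::tibble(
    spot_id = integer(0), channel = character(0), row = numeric(0),
    col = numeric(0), n_fluorophores = integer(0),
    bleach_frames = list(), unit_intensity = numeric(0)
  )
  structure(
    list(
      cy3 = if (is.null(spots)) empty else spots,
      cy5 = empty,
      pairs = tibble::tibble(cy3_id = integer(0), cy5_id = integer(0)),
      dim = dim, pixel_size = pixel_size, n_frames = n_frames,
      frame_interval = frame_interval,
      spec = condition_spec("encoded")
    ),
    class = "spot_field"
  )
}

spot_row <- function(row, col, n = 1, bleach = list(integer(0)),
                     unit = 3000) {
  tibble::tibble(
    spot_id = 1L, channel = "Cy3", row = row, col = col,
    n_fluorophores = as.integer(n), bleach_frames = bleach,
    unit_intensity = unit
  )
}
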
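#' Extract the integrated-intensity trace of one AOI
#'
#' The trace value at frame `t` is the sum of the fixed odd-sized pixel
#' window centered on the AOI, in arbitrary units (AU).
#'
#' @param stack An [image_stack()] (normally background-subtracted).
#' @param row,col AOI center pixel, 0-based.
#' @param aoi_size Window edge in px (odd).
#' @return A numeric vector of length `n_frames(stack)`.
#' @export
extract_trace <- function(stack, row, col, aoi_size = 7) {
  stopifnot(inherits(stack, "image_stack"))
  half <- (aoi_size - 1) / 2
  d <- frame_dim(stack)
  if (row - half < 0 || row + half > d[1] - 1 ||
    col - half < 0 || col + half > d[2] - 1) {
    abort("AOI window leaves the frame")
  }
  rows <- (row - half):(row + half) + 1
  cols <- (col - half):(col + half) + 1
  apply(stack[, rows, cols, drop = FALSE], 1, sum)
}

#' Extract traces for a table of AOIs
#'
#' @param stack An [image_stack()].
#' @param aois AOI tibble from [detect_spots()].
#' @param aoi_size Window edge in px (odd).
#' @return A long tibble: `aoi_id`, `frame` (0-based), `intensity` (AU).
#' @export
extract_traces <- function(stack, aois, aoi_size = 7) {
  purrr::map_dfr(seq_len(nrow(aois)), function(i) {
    v <- extract_trace(stack, aois$row[i], aois$col[i], aoi_size)
    tibble::tibble(
      aoi_id = aois$id[i], frame = seq_along(v) - 1L,
      intensity = v
    )
  })
}

#' Robust trace noise estimate
#'
#' Estimates the frame-to-frame noise standard deviation from the median
#' absolute successive difference, scaled by 1.4826 (Gaussian consistency)
#' and divided by sqrt(2) (a difference of two independent noise terms).
#' Insensitive to the small number of genuine bleaching steps in a trace.
#'
#' @param values Numeric trace.
#' @return Estimated noise sd (AU).
#' @export
estimate_noise_sd <- function(values) {
  d <- diff(values)
  if (!length(d)) return(0)
  1.4826 * median(abs(d)) / sqrt(2)
}

# Best single split of v[lo:hi]: returns split index i (split between i and
# i+1, 1-based) maximizing the SSE reduction, with the reduction and the two
# sub-segment means. Vectorized via cumulative sums.
best_split <- function(v, lo, hi) {
  n <- hi - lo + 1
  if (n < 2) return(NULL)
  x <- v[lo:hi]
  cs <- cumsum(x)
  tot <- cs[n]
  k <- seq_len(n - 1)
  # SSE reduction of splitting after position k (within-segment)
  red <- cs[k]^2 / k + (tot - cs[k])^2 / (n - k) - tot^2 / n
  j <- which.max(red)
  list(
    split = lo + j - 1,
    reduction = red[j],
    mean_left = cs[j] / j,
    mean_right = (tot - cs[j]) / (n - j)
  )
}

segment_bounds <- function(cps, T) {
  starts <- c(1L, cps + 1L)
  ends <- c(cps, T)
  cbind(starts, ends)
}

segment_means <- function(v, cps) {
  b <- segment_bounds(cps, length(v))
  vapply(seq_len(nrow(b)), function(i) mean(v[b[i, 1]:b[i, 2]]), numeric(1))
}

segment_sse <- function(v, cps) {
  b <- segment_bounds(cps, length(v))
  sum(vapply(seq_len(nrow(b)), function(i) {
    x <- v[b[i, 1]:b[i, 2]]
    sum((x - mean(x))^2)
  }, numeric(1)))
}

best_insertion <- function(v, cps, T) {
  b <- segment_bounds(cps, T)
  cand <- NULL
  for (i in seq_len(nrow(b))) {
    s <- best_split(v, b[i, 1], b[i, 2])
    if (is.null(s)) next
    if (is.null(cand) || s$reduction > cand$reduction) cand <- s
  }
  cand
}

refine_cps <- function(v, cps, T) {
  for (sweep in 1:10) {
    moved <- FALSE
    for (j in seq_along(cps)) {
      lo <- if (j == 1) 1L else cps[j - 1] + 1L
      hi <- if (j == length(cps)) T else cps[j + 1]
      s <- best_split(v, lo, hi)
      if (!is.null(s) && s$split != cps[j]) {
        cps[j] <- s$split
        moved <- TRUE
      }
    }
    if (!moved) break
  }
  cps
}

# Greedy penalized step placement with local changepoint refinement and a
# two-step lookahead: when the best single insertion fails the gates, a
# jointly beneficial pair of change points (e.g. a short excursion that no
# single step can explain) is still accepted if the pair clears twice the
# penalty and every resulting step amplitude clears the SNR gate.
fit_steps_greedy <- function(v, sigma, lambda, min_step_snr, max_steps) {
  T <- length(v)
  penalty <- lambda * sigma^2 * log(T)
  zero_tol <- max(1e-9, 1e-12 * sum(v^2))
  cps <- integer(0)
  repeat {
    if (length(cps) >= max_steps) break
    cand <- best_insertion(v, cps, T)
    if (is.null(cand)) break
    amp <- abs(cand$mean_right - cand$mean_left)
    if (sigma > 0) {
      single_ok <- cand$reduction > penalty && amp >= min_step_snr * sigma
      if (!single_ok) {
        pair <- lookahead_pair(v, cps, cand, T, penalty, min_step_snr * sigma)
        if (is.null(pair)) break
        cps <- pair
        next
      }
    } else {
      if (cand$reduction <= zero_tol) break
    }
    cps <- refine_cps(v, sort(c(cps, cand$split)), T)
  }
  cps
}

lookahead_pair <- function(v, cps, cand, T, penalty, min_amp) {
  if (length(cps) + 2 > T - 1) return(NULL)
  sse_before <- segment_sse(v, cps)
  tentative <- sort(c(cps, cand$split))
  second <- best_insertion(v, tentative, T)
  if (is.null(second)) return(NULL)
  trial <- refine_cps(v, sort(c(tentative, second$split)), T)
  if (anyDuplicated(trial)) return(NULL)
  reduction <- sse_before - segment_sse(v, trial)
  if (reduction <= 2 * penalty) return(NULL)
  if (any(abs(diff(segment_means(v, trial))) < min_amp)) return(NULL)
  trial
}

#' Count photobleaching steps in an intensity trace
#'
#' Fits a piecewise-constant description of the trace by iterative greedy
#' step placement: the change point giving the largest variance reduction is
#' inserted repeatedly, with each insertion followed by local refinement of
#' all change-point locations, until the candidate step's amplitude falls
#' below `min_step_snr` noise standard deviations or the penalized cost
#' (per-step penalty `lambda * sigma^2 * log(T)`) stops decreasing.
#'
#' Classification then mirrors the manual convention for photobleaching
#' traces: only traces whose fitted levels are strictly decreasing (every
#' step downward) and that bleach to completion are accepted. A fitted
#' upward step flags blinking or aggregation (`rejection_reason =
#' "upward_step"`); a final level that stays clearly above baseline flags an
#' incompletely bleached spot (`"never_bleached"`). The baseline test
#' accepts a final level within `z_tol` standard errors of zero, or within
#' `baseline_frac` of the smallest fitted step amplitude — the latter
#' allowance absorbs the small positive offset that zero-clipping of
#' background-subtracted pixels leaves in integrated traces.
#'
#' @param values Numeric trace (length >= 5), or a tibble with an
#'   `intensity` column.
#' @param noise_sd Frame noise sd; estimated by [estimate_noise_sd()] when
#'   `NULL`.
#' @param lambda Per-step penalty constant (default 3).
#' @param min_step_snr Minimum step amplitude in units of `noise_sd`
#'   (default 2).
#' @param max_steps Cap on fitted steps.
#' @param z_tol Baseline z tolerance (default 3).
#' @param baseline_frac Baseline allowance as a fraction of the smallest
#'   step amplitude (default 0.5).
#' @return A `step_fit` object: `n_steps`, `change_frames` (0-based frame at
#'   which each new level starts), `levels` (segment means, AU), `accepted`,
#'   `rejection_reason` (`"upward_step"`, `"never_bleached"` or `"none"`),
#'   `sigma`, and the input `values`.
#' @export
count_bleach_steps <- function(values, noise_sd = NULL, lambda = 3,
                               min_step_snr = 2, max_steps = 10,
                               z_tol = 3, baseline_frac = 0.5) {
  if (is.data.frame(values)) values <- values$intensity
  if (all(is.na(values))) abort("trace is all NA")
  if (length(values) < 5) abort("trace must have at least 5 frames")
  sigma <- noise_sd %||% estimate_noise_sd(values)
  if (sigma < 0) abort("`noise_sd` must be >= 0")

  cps <- fit_steps_greedy(values, sigma, lambda, min_step_snr, max_steps)
  levels <- segment_means(values, cps)
  steps <- diff(levels)
  n <- length(cps)

  reason <- "none"
  if (n == 0) {
    reason <- "never_bleached"
  } else if (any(steps > 0)) {
    reason <- "upward_step"
  } else {
    n_last <- length(values) - cps[n]
    tol <- max(
      z_tol * sigma / sqrt(n_last),
      baseline_frac * min(abs(steps))
    )
    if (levels[n + 1] > tol) reason <- "never_bleached"
  }
  structure(
    list(
      n_steps = n, change_frames = as.integer(cps), levels = levels,
      accepted = reason == "none", rejection_reason = reason,
      sigma = sigma, values = values
    ),
    class = "step_fit"
  )
}

#' @export
print.step_fit <- function(x, ...) {
  cat(sprintf(
    "<step_fit> %d step(s) at frame(s) %s; %s (sigma = %.3g)\n",
    x$n_steps, paste(x$change_frames, collapse = ", "),
    if (x$accepted) "accepted" else paste0("rejected: ", x$rejection_reason),
    x$sigma
  ))
  invisible(x)
}

#' Fit bleaching steps for every AOI of a movie
#'
#' @param stack A background-subtracted [image_stack()].
#' @param aois AOI tibble from [detect_spots()].
#' @param aoi_size Window edge in px.
#' @param ... Passed to [count_bleach_steps()].
#' @return A tibble: `aoi_id`, `n_steps`, `accepted`, `rejection_reason`,
#'   `sigma`, and a `fit` list-column of `step_fit` objects.
#' @export
fit_traces <- function(stack, aois, aoi_size = 7, ...) {
  purrr::map_dfr(seq_len(nrow(aois)), function(i) {
    v <- extract_trace(stack, aois$row[i], aois$col[i], aoi_size)
    f <- count_bleach_steps(v, ...)
    tibble::tibble(
      aoi_id = aois$id[i], n_steps = f$n_steps, accepted = f$accepted,
      rejection_reason = f$rejection_reason, sigma = f$sigma, fit = list(f)
    )
  })
}

#' Aggregate accepted step counts into a histogram
#'
#' Mirrors the per-movie / per-oocyte pooling convention: absolute step
#' counts are pooled across movies; the relative occurrence of each step
#' number is computed per movie, averaged per oocyte, and then pooled across
#' oocytes as mean ± s.e.m. Study designs use the same number of movies per
#' condition so absolute histograms are comparable between conditions.
#'
#' @param fits A tibble with columns `oocyte`, `movie`, `n_steps`,
#'   `accepted` (one row per trace).
#' @param condition Optional condition label.
#' @param max_step Histogram upper bound; defaults to the largest observed
#'   step count.
#' @return A `step_histogram`: tibbles `absolute` (`n_steps`, `count`),
#'   `per_movie` and `per_oocyte` relative frequencies, and `pooled`
#'   (`n_steps`, `mean`, `sem`), plus `n_traces` and `n_oocytes`.
#' @export
aggregate_step_histogram <- function(fits, condition = NULL,
                                     max_step = NULL) {
  req <- c("oocyte", "movie", "n_steps", "accepted")
  if (!all(req %in% names(fits))) {
    abort("`fits` needs columns oocyte, movie, n_steps, accepted")
  }
  acc <- dplyr::filter(fits, .data$accepted, .data$n_steps >= 1)
  if (nrow(acc) == 0) abort("no accepted traces to aggregate")
  K <- max_step %||% max(acc$n_steps)
  grid <- tidyr::expand_grid(
    dplyr::distinct(acc, .data$oocyte, .data$movie),
    n_steps = seq_len(K)
  )
  per_movie <- acc |>
    dplyr::count(.data$oocyte, .data$movie, .data$n_steps, name = "count") |>
    dplyr::right_join(grid, by = c("oocyte", "movie", "n_steps")) |>
    dplyr::mutate(count = tidyr::replace_na(.data$count, 0L)) |>
    dplyr::group_by(.data$oocyte, .data$movie) |>
    dplyr::mutate(rel = .data$count / sum(.data$count)) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$oocyte, .data$movie, .data$n_steps)
  per_oocyte <- per_movie |>
    dplyr::group_by(.data$oocyte, .data$n_steps) |>
    dplyr::summarise(rel = mean(.data$rel), .groups = "drop")
  pooled <- per_oocyte |>
    dplyr::group_by(.data$n_steps) |>
    dplyr::summarise(
      mean = mean(.data$rel),
      sem = if (dplyr::n() > 1) sd(.data$rel) / sqrt(dplyr::n()) else NA_real_,
      .groups = "drop"
    )
  absolute <- per_movie |>
    dplyr::group_by(.data$n_steps) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop")
  structure(
    list(
      condition = condition, absolute = absolute, per_movie = per_movie,
      per_oocyte = per_oocyte, pooled = pooled,
      n_traces = nrow(acc), n_oocytes = dplyr::n_distinct(acc$oocyte)
    ),
    class = "step_histogram"
  )
}

#' @export
print.step_histogram <- function(x, ...) {
  cat(sprintf(
    "<step_histogram>%s %d accepted trace(s), %d oocyte(s)\n",
    if (is.null(x$condition)) "" else paste0(" [", x$condition, "]"),
    x$n_traces, x$n_oocytes
  ))
  print(x$pooled)
  invisible(x)
}

#' Per-step-number comparison of two step histograms
#'
#' For each step number, a two-sample equal-variance two-tailed t-test is
#' applied to the per-oocyte relative frequencies of the two conditions.
#'
#' @param hist_a,hist_b `step_histogram` objects with >= 2 oocytes each.
#' @return A tibble: `n_steps`, `mean_a`, `mean_b`, `t`, `df`, `p`.
#' @export
compare_step_distributions <- function(hist_a, hist_b) {
  stopifnot(
    inherits(hist_a, "step_histogram"),
    inherits(hist_b, "step_histogram")
  )
  if (hist_a$n_oocytes < 2 || hist_b$n_oocytes < 2) {
    abort("need at least 2 oocytes per condition")
  }
  K <- max(hist_a$per_oocyte$n_steps, hist_b$per_oocyte$n_steps)
  freqs <- function(h, k) {
    h$per_oocyte |>
      dplyr::group_by(.data$oocyte) |>
      dplyr::summarise(
        rel = sum(.data$rel[.data$n_steps == k]),
        .groups = "drop"
      ) |>
      dplyr::pull(.data$rel)
  }
  purrr::map_dfr(seq_len(K), function(k) {
    a <- freqs(hist_a, k)
    b <- freqs(hist_b, k)
    tt <- two_sample_ttest(a, b)
    tibble::tibble(
      n_steps = k, mean_a = mean(a), mean_b = mean(b),
      t = tt$t, df = tt$df, p = tt$p
    )
  })
}
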
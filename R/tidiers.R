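#' Tidy a step fit into one row per fitted segment
#'
#' @param x A `step_fit` from [count_bleach_steps()].
#' @param ... Unused.
#' @return A tibble: `segment`, `start_frame`, `end_frame` (0-based,
#'   inclusive), `level` (AU), `step` (drop from the previous level, `NA`
#'   for the first segment).
#' @export
tidy.step_fit <- function(x, ...) {
  T <- length(x$values)
  starts <- c(0L, x$change_frames)
  ends <- c(x$change_frames - 1L, T - 1L)
  tibble::tibble(
    segment = seq_along(starts),
    start_frame = starts, end_frame = ends,
    level = x$levels,
    step = c(NA_real_, diff(x$levels))
  )
}

#' One-row summary of a step fit
#'
#' @param x A `step_fit`.
#' @param ... Unused.
#' @return A tibble: `n_steps`, `accepted`, `rejection_reason`, `sigma`,
#'   `initial_level`, `final_level`.
#' @export
glance.step_fit <- function(x, ...) {
  tibble::tibble(
    n_steps = x$n_steps, accepted = x$accepted,
    rejection_reason = x$rejection_reason, sigma = x$sigma,
    initial_level = x$levels[1],
    final_level = x$levels[length(x$levels)]
  )
}

#' Tidy a step histogram into its pooled per-step summary
#'
#' @param x A `step_histogram` from [aggregate_step_histogram()].
#' @param ... Unused.
#' @return A tibble: `n_steps`, `count` (pooled absolute), `mean`, `sem`
#'   (pooled relative frequency across oocytes).
#' @export
tidy.step_histogram <- function(x, ...) {
  dplyr::full_join(x$absolute, x$pooled, by = "n_steps") |>
    dplyr::arrange(.data$n_steps)
}

#' One-row summary of a step histogram
#'
#' @param x A `step_histogram`.
#' @param ... Unused.
#' @return A tibble: `condition`, `n_traces`, `n_oocytes`, `max_step`,
#'   `frac_multi` (pooled relative frequency of 2+ steps).
#' @export
glance.step_histogram <- function(x, ...) {
  tibble::tibble(
    condition = x$condition %||% NA_character_,
    n_traces = x$n_traces, n_oocytes = x$n_oocytes,
    max_step = max(x$pooled$n_steps),
    frac_multi = sum(x$pooled$mean[x$pooled$n_steps >= 2])
  )
}

#' Tidy a colocalization result
#'
#' @param x A `coloc_result` from [coloc_analysis()].
#' @param ... Unused.
#' @return A long tibble: `statistic` (`observed`, `null`, `corrected`),
#'   `fraction`, `n_cy5`, `n_coloc`.
#' @export
tidy.coloc_result <- function(x, ...) {
  tibble::tibble(
    statistic = c("observed", "null", "corrected"),
    fraction = c(x$fraction, x$null_fraction, x$corrected_fraction),
    n_cy5 = c(x$n_cy5, x$null_n_cy5, NA_integer_),
    n_coloc = c(x$n_coloc, x$null_n_coloc, NA_integer_)
  )
}
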
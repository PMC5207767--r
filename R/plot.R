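#' Plot an intensity trace with its fitted steps
#'
#' Shows the integrated AOI intensity versus frame with the fitted
#' piecewise-constant levels overlaid, the standard presentation of a
#' photobleaching trace.
#'
#' @param object A `step_fit` from [count_bleach_steps()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.step_fit <- function(object, ...) {
  trace <- tibble::tibble(
    frame = seq_along(object$values) - 1L,
    intensity = object$values
  )
  seg <- tidy(object)
  ggplot2::ggplot(trace, ggplot2::aes(x = .data$frame, y = .data$intensity)) +
    ggplot2::geom_line(colour = "grey50", linewidth = 0.3) +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(
        x = .data$start_frame, xend = .data$end_frame,
        y = .data$level, yend = .data$level
      ),
      colour = "red", linewidth = 0.8
    ) +
    ggplot2::labs(
      x = "frame", y = "integrated intensity (AU)",
      subtitle = sprintf(
        "%d step(s), %s", object$n_steps,
        if (object$accepted) "accepted" else object$rejection_reason
      )
    ) +
    ggplot2::theme_minimal()
}

#' Plot a pooled step histogram
#'
#' Relative occurrence of each step number, pooled across oocytes, with
#' s.e.m. error bars.
#'
#' @param object A `step_histogram` from [aggregate_step_histogram()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.step_histogram <- function(object, ...) {
  ggplot2::ggplot(
    object$pooled,
    ggplot2::aes(x = factor(.data$n_steps), y = .data$mean)
  ) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::geom_errorbar(
      ggplot2::aes(
        ymin = .data$mean - .data$sem,
        ymax = .data$mean + .data$sem
      ),
      width = 0.2, na.rm = TRUE
    ) +
    ggplot2::labs(
      x = "photobleaching steps", y = "relative occurrence",
      subtitle = object$condition
    ) +
    ggplot2::theme_minimal()
}

#' Overlay detected AOIs on an image frame
#'
#' @param frame A 2-D matrix (typically the background-subtracted first
#'   frame).
#' @param aois AOI tibble from [detect_spots()].
#' @param aoi_size AOI window edge in px drawn around each center.
#' @return A ggplot.
#' @export
plot_spot_overlay <- function(frame, aois, aoi_size = 7) {
  df <- tibble::tibble(
    row = rep(seq_len(nrow(frame)) - 1L, times = ncol(frame)),
    col = rep(seq_len(ncol(frame)) - 1L, each = nrow(frame)),
    intensity = as.vector(frame)
  )
  half <- (aoi_size - 1) / 2
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::geom_rect(
      data = aois,
      ggplot2::aes(
        xmin = .data$col - half, xmax = .data$col + half,
        ymin = .data$row - half, ymax = .data$row + half
      ),
      inherit.aes = FALSE, colour = "yellow", fill = NA, linewidth = 0.3
    ) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
}
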
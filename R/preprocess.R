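#' Ball structuring element for grayscale morphology
#'
#' The spherical-cap structuring element used by [rolling_ball_background()]:
#' offsets within `radius` of the origin, with heights
#' `height_scale * sqrt(radius^2 - d^2)`. With `height_scale = 1` the element
#' is geometrically spherical in (x, y, intensity) under the convention of
#' 1 AU per px.
#'
#' @param radius Ball radius in px (>= 1).
#' @param height_scale Intensity units per px of ball height.
#' @return A list with integer offset vectors `dr`, `dc` and `height`.
#' @export
ball_element <- function(radius, height_scale = 1) {
  if (radius < 1) abort("`radius` must be >= 1")
  d <- seq(-floor(radius), floor(radius))
  grid <- expand.grid(dr = d, dc = d)
  keep <- grid$dr^2 + grid$dc^2 <= radius^2
  grid <- grid[keep, ]
  list(
    dr = as.integer(grid$dr), dc = as.integer(grid$dc),
    height = height_scale * sqrt(radius^2 - grid$dr^2 - grid$dc^2)
  )
}

#' Rolling-ball background estimation
#'
#' Estimates the smooth image background as the grayscale morphological
#' opening of the frame with a ball (spherical cap) structuring element:
#' erosion followed by the adjoint dilation. The background never exceeds
#' the frame, retains smooth features wider than the ball, and suppresses
#' features narrower than the ball — the classical rolling-ball model of
#' diffraction-limited spots riding on slowly varying background. The
#' default radius of 50 px matches standard practice for sparse
#' single-molecule fields. Note this is the exact morphological operator;
#' ImageJ's implementation uses a paraboloid approximation with optional
#' pre-smoothing, so results differ in detail.
#'
#' @param frame A 2-D numeric matrix.
#' @param radius Ball radius in px; must not exceed both image dimensions.
#' @param height_scale Ball height scaling, AU per px (see [ball_element()]).
#' @param smooth If `TRUE`, a 3x3 mean filter is applied to the frame before
#'   estimating the background (the background is still subtracted from the
#'   unsmoothed frame by [subtract_stack()]).
#' @return The background image, same dimensions as `frame`.
#' @export
rolling_ball_background <- function(frame, radius = 50, height_scale = 1,
                                    smooth = FALSE) {
  if (!is.matrix(frame)) abort("`frame` must be a 2-D matrix")
  if (radius > nrow(frame) && radius > ncol(frame)) {
    abort("`radius` exceeds both image dimensions")
  }
  f <- frame
  if (smooth) f <- mean_filter3(f)
  el <- ball_element(radius, height_scale)
  eroded <- cpp_erode(f, el$dr, el$dc, el$height)
  cpp_dilate(eroded, el$dr, el$dc, el$height)
}

mean_filter3 <- function(m) {
  H <- nrow(m); W <- ncol(m)
  # replicate-padded 3x3 mean
  rp <- rbind(m[1, , drop = FALSE], m, m[H, , drop = FALSE])
  rp <- cbind(rp[, 1, drop = FALSE], rp, rp[, W, drop = FALSE])
  acc <- matrix(0, H, W)
  for (di in 0:2) {
    for (dj in 0:2) {
      acc <- acc + rp[di + seq_len(H), dj + seq_len(W)]
    }
  }
  acc / 9
}

#' Subtract an estimated background from a frame
#'
#' Computes `max(frame - background, 0)` pointwise. Negative residuals are
#' clipped to zero, so the output is always within `[0, frame]` when the
#' background came from a morphological opening (which is anti-extensive).
#'
#' @param frame A 2-D numeric matrix.
#' @param background A matrix of the same dimensions.
#' @return The corrected frame.
#' @export
subtract_background <- function(frame, background) {
  if (!identical(dim(frame), dim(background))) {
    abort("`frame` and `background` must have the same dimensions")
  }
  pmax(frame - background, 0)
}

#' Estimate the image background, optionally recentered
#'
#' The morphological opening rides along the lower noise envelope of the
#' image, so on a noisy frame it sits systematically a few noise standard
#' deviations below the true background level; left uncorrected, that bias
#' accumulates over an integrated AOI into an offset comparable to one
#' fluorophore's intensity. `recenter = TRUE` (the default) removes it by
#' shifting the opening up by the median of `frame - opening`: spots are
#' sparse, so the median residual estimates the noise-envelope gap and the
#' corrected frame has median ~0.
#'
#' @inheritParams rolling_ball_background
#' @param recenter Shift the opening by the median residual (default TRUE).
#' @return The background image.
#' @export
estimate_background <- function(frame, radius = 50, height_scale = 1,
                                smooth = FALSE, recenter = TRUE) {
  bg <- rolling_ball_background(frame, radius, height_scale, smooth = smooth)
  if (recenter) bg <- bg + median(frame - bg)
  bg
}

#' Background-subtract a whole stack
#'
#' By default the background is estimated once on the first frame and reused
#' for every frame: spots bleach over the movie but the cellular background
#' is static on this timescale, and a shared background keeps trace baselines
#' consistent. Per-frame estimation is available.
#'
#' @param stack An [image_stack()].
#' @inheritParams estimate_background
#' @param per_frame If `TRUE`, re-estimate the background on every frame.
#' @return The corrected `image_stack`.
#' @export
subtract_stack <- function(stack, radius = 50, height_scale = 1,
                           smooth = FALSE, recenter = TRUE,
                           per_frame = FALSE) {
  stopifnot(inherits(stack, "image_stack"))
  out <- unclass(stack)
  bg <- estimate_background(get_frame(stack, 0), radius, height_scale,
    smooth = smooth, recenter = recenter
  )
  for (t in seq_len(n_frames(stack))) {
    if (per_frame && t > 1) {
      bg <- estimate_background(
        get_frame(stack, t - 1), radius, height_scale,
        smooth = smooth, recenter = recenter
      )
    }
    out[t, , ] <- subtract_background(stack[t, , ], bg)
  }
  image_stack(out,
    pixel_size = attr(stack, "pixel_size"),
    frame_interval = attr(stack, "frame_interval"),
    channel = attr(stack, "channel")
  )
}
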
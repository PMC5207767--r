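#' Construct a time-lapse image stack
#'
#' An `image_stack` is a `T x H x W` array of non-negative intensities in
#' arbitrary grayscale units (AU), carrying the physical metadata every
#' downstream computation needs: the pixel size in micrometres per pixel, the
#' frame interval in seconds, and the channel label.
#'
#' @param frames A `T x H x W` numeric array, a single `H x W` matrix (treated
#'   as a one-frame stack), or a list of equally sized matrices.
#' @param pixel_size Pixel edge length in µm/px. Must be positive.
#' @param frame_interval Time between frames in seconds.
#' @param channel Channel label, typically `"Cy3"` or `"Cy5"`.
#' @return An object of class `image_stack`: the array with metadata
#'   attributes.
#' @export
image_stack <- function(frames, pixel_size = 0.2, frame_interval = 1,
                        channel = "Cy3") {
  if (is.matrix(frames)) {
    frames <- array(frames, dim = c(1L, nrow(frames), ncol(frames)))
  } else if (is.list(frames)) {
    dims <- unique(lapply(frames, dim))
    if (length(dims) != 1) abort("all frames must have the same dimensions")
    arr <- array(0, dim = c(length(frames), dims[[1]][1], dims[[1]][2]))
    for (t in seq_along(frames)) arr[t, , ] <- frames[[t]]
    frames <- arr
  }
  if (!is.array(frames) || length(dim(frames)) != 3) {
    abort("`frames` must be a T x H x W array, a matrix, or a list of matrices")
  }
  if (dim(frames)[1] < 1) abort("a stack needs at least one frame")
  if (!all(is.finite(frames))) abort("stack intensities must be finite")
  if (!is.numeric(pixel_size) || pixel_size <= 0) {
    abort("`pixel_size` must be a positive number (um/px)")
  }
  structure(frames,
    pixel_size = pixel_size, frame_interval = frame_interval,
    channel = channel, class = c("image_stack", "array")
  )
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x)
  cat(sprintf(
    "<image_stack> %d frame(s), %d x %d px, %.3g um/px, %.3g s/frame, channel %s\n",
    d[1], d[2], d[3], attr(x, "pixel_size"), attr(x, "frame_interval"),
    attr(x, "channel")
  ))
  invisible(x)
}

#' Number of frames and frame dimensions of a stack
#' @param stack An `image_stack`.
#' @return `n_frames()`: integer frame count. `frame_dim()`: `c(H, W)` in px.
#' @export
n_frames <- function(stack) dim(stack)[1]

#' @rdname n_frames
#' @export
frame_dim <- function(stack) dim(stack)[2:3]

#' Extract one frame from a stack
#' @param stack An `image_stack`.
#' @param t Frame index, 0-based (frame 0 is the first acquired frame).
#' @return An `H x W` matrix.
#' @export
get_frame <- function(stack, t = 0) {
  stopifnot(t >= 0, t < n_frames(stack))
  stack[t + 1, , ]
}

#' Read and write multi-page 16-bit TIFF stacks
#'
#' Stacks are stored as multi-page grayscale TIFFs with one file per channel,
#' the format produced by EMCCD acquisition software. Values are read back as
#' integer grayscale units (0-65535). Pixel size and frame interval are not
#' stored in the TIFF and must be supplied.
#'
#' @param path File path.
#' @inheritParams image_stack
#' @return `read_stack()` returns an `image_stack`; `write_stack()` returns
#'   `path` invisibly.
#' @export
read_stack <- function(path, pixel_size = 0.2, frame_interval = 1,
                       channel = "Cy3") {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3) p <- p[, , 1]
    storage.mode(p) <- "double"
    p
  })
  image_stack(pages,
    pixel_size = pixel_size, frame_interval = frame_interval,
    channel = channel
  )
}

#' @rdname read_stack
#' @param stack An `image_stack` with values in 0-65535.
#' @export
write_stack <- function(stack, path) {
  pages <- lapply(seq_len(n_frames(stack)), function(t) {
    m <- get_frame(stack, t - 1)
    m <- pmin(pmax(round(m), 0), 65535)
    m / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}
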
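#' Analyze one background-subtracted movie end to end
#'
#' Runs the per-movie pipeline on a single channel: detect spots in the
#' first frame, extract integrated AOI traces, and count bleaching steps.
#'
#' @param stack A background-subtracted [image_stack()].
#' @param params A [detection_params()]; the default threshold follows the
#'   stack's channel preset.
#' @param ... Passed to [count_bleach_steps()].
#' @return A list: `aois` (tibble), `fits` (tibble from [fit_traces()]),
#'   `density` (spots/µm²).
#' @export
analyze_stack <- function(stack, params = NULL, ...) {
  channel <- attr(stack, "channel")
  params <- params %||%
    detection_params(intensity_threshold = default_threshold(channel))
  first <- get_frame(stack, 0)
  aois <- detect_spots(first, params, channel = channel)
  fits <- if (nrow(aois)) {
    fit_traces(stack, aois, aoi_size = params$aoi_size, ...)
  } else {
    tibble::tibble(
      aoi_id = integer(0), n_steps = integer(0), accepted = logical(0),
      rejection_reason = character(0), sigma = numeric(0), fit = list()
    )
  }
  list(
    aois = aois,
    fits = fits,
    n_spots = count_spots(first, params),
    density = density_estimate(
      count_spots(first, params), frame_dim(stack),
      attr(stack, "pixel_size"),
      resolution_px = params$split_sep
    )
  )
}

#' Simulate and analyze a full encoded-or-mock experiment
#'
#' For each simulated oocyte and movie: generate the ground-truth spot
#' field, render both channels with camera noise, rolling-ball subtract,
#' detect spots, fit bleaching steps, and score two-channel colocalization.
#' This is the synthetic counterpart of a complete imaging session and the
#' harness for end-to-end parameter-recovery checks.
#'
#' @param spec A [condition_spec()].
#' @param camera A [camera_model()].
#' @param n_oocytes Number of simulated oocytes.
#' @param movies_per_oocyte Movies per oocyte.
#' @param dim Field dimensions `c(H, W)` px.
#' @param pixel_size Pixel size, µm/px.
#' @param n_frames Frames per movie.
#' @param radius Rolling-ball radius, px.
#' @param seed Master seed; per-movie child seeds are derived from it.
#' @param tolerance Colocalization match distance, px.
#' @param offset Registration offset passed to [coloc_analysis()]; defaults
#'   to the spec's true offset (`NULL` estimates it from the data).
#' @param ... Passed to [count_bleach_steps()].
#' @return A list of tibbles: `movies` (oocyte, movie, channel, n_spots,
#'   density, true density), `fits` (per-trace step fits with oocyte/movie
#'   labels, plus true fluorophore counts of matched ground-truth spots),
#'   `coloc` (per-movie colocalization rows).
#' @export
run_condition_experiment <- function(spec, camera = camera_model(),
                                     n_oocytes = 5, movies_per_oocyte = 1,
                                     dim = c(128, 128), pixel_size = 0.2,
                                     n_frames = 100, radius = 50,
                                     seed = 1, tolerance = 2,
                                     offset = spec$registration_offset,
                                     ...) {
  movies <- list(); fits <- list(); coloc <- list()
  idx <- 0
  for (oo in seq_len(n_oocytes)) {
    for (mv in seq_len(movies_per_oocyte)) {
      idx <- idx + 1
      mseed <- child_seed(seed, idx)
      field <- simulate_spot_field(spec, dim, pixel_size,
        n_frames = n_frames, frame_interval = camera$frame_interval,
        seed = child_seed(mseed, 1)
      )
      res <- list()
      for (ch in c("Cy3", "Cy5")) {
        stack <- render_movie(field, camera, ch,
          seed = child_seed(mseed, if (ch == "Cy3") 2 else 3)
        )
        stack <- subtract_stack(stack, radius = radius)
        res[[ch]] <- analyze_stack(stack, ...)
        truth <- if (ch == "Cy3") field$cy3 else field$cy5
        movies[[length(movies) + 1]] <- tibble::tibble(
          oocyte = oo, movie = mv, channel = ch,
          n_spots = res[[ch]]$n_spots,
          n_aois = nrow(res[[ch]]$aois),
          density = res[[ch]]$density,
          true_n_spots = nrow(truth),
          true_density = if (ch == "Cy3") spec$density_cy3 else spec$density_cy5
        )
        if (nrow(res[[ch]]$fits)) {
          f <- res[[ch]]$fits
          f$true_n_fluor <- match_truth(res[[ch]]$aois, truth)
          f$oocyte <- oo; f$movie <- mv; f$channel <- ch
          fits[[length(fits) + 1]] <- f[, c(
            "oocyte", "movie", "channel", "aoi_id", "n_steps", "accepted",
            "rejection_reason", "sigma", "true_n_fluor"
          )]
        }
      }
      cl <- coloc_analysis(res$Cy3$aois, res$Cy5$aois, dim,
        offset = offset, tolerance = tolerance
      )
      cl$oocyte <- oo; cl$movie <- mv
      coloc[[length(coloc) + 1]] <- cl
    }
  }
  list(
    movies = dplyr::bind_rows(movies),
    fits = dplyr::bind_rows(fits),
    coloc = dplyr::bind_rows(coloc)
  )
}

# Match detected AOIs to ground-truth spots (nearest within 2 px, Euclidean);
# returns the true fluorophore count or NA for unmatched detections.
match_truth <- function(aois, truth, radius = 2) {
  vapply(seq_len(nrow(aois)), function(i) {
    if (!nrow(truth)) return(NA_integer_)
    d2 <- (truth$row - aois$row[i])^2 + (truth$col - aois$col[i])^2
    j <- which.min(d2)
    if (d2[j] <= radius^2) truth$n_fluorophores[j] else NA_integer_
  }, integer(1))
}
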
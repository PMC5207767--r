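#' Experimental condition presets for the synthetic movie generator
#'
#' A `condition_spec` bundles the parameters that distinguish the two study
#' conditions seen in encoded-vs-mock TIRF experiments: the spot number
#' density per channel, the fraction of Cy5 spots that truly carry a Cy3
#' partner, the distribution of fluorophores per spot, the photobleaching
#' rate, and the residual channel registration offset.
#'
#' Preset densities follow the reported membrane densities: encoded Cy3
#' 0.14 spots/µm² and Cy5 0.08, mock Cy3 0.03 and Cy5 0.02. The encoded
#' fluorophore-count distribution is shifted towards 2+ fluorophores per spot
#' (dimeric channels, plus clusters), while the mock distribution puts most
#' of its mass on single fluorophores.
#'
#' @param condition `"encoded"` or `"mock"`.
#' @param density_cy3,density_cy5 Spot densities in spots/µm².
#' @param colocalized_fraction Fraction of Cy5 spots placed at a Cy3 spot
#'   position (plus the registration offset); in `[0, 1]`.
#' @param fluor_count_distribution Probability vector over 1..K fluorophores
#'   per spot; must sum to 1.
#' @param bleach_rate Per-fluorophore photobleaching rate in 1/s.
#' @param registration_offset Integer `(d_row, d_col)` offset of the Cy5
#'   field relative to the Cy3 field, in px; components bounded by 3 px.
#' @param unit_intensity Integrated intensity of one fluorophore, AU.
#' @return A `condition_spec` list.
#' @export
condition_spec <- function(condition = c("encoded", "mock"),
                           density_cy3 = NULL, density_cy5 = NULL,
                           colocalized_fraction = NULL,
                           fluor_count_distribution = NULL,
                           bleach_rate = 0.03,
                           registration_offset = c(1, 2),
                           unit_intensity = 3000) {
  condition <- match.arg(condition)
  defaults <- if (condition == "encoded") {
    list(
      density_cy3 = 0.14, density_cy5 = 0.08,
      colocalized_fraction = 0.12,
      fluor_count_distribution = c(0.35, 0.30, 0.20, 0.10, 0.05)
    )
  } else {
    list(
      density_cy3 = 0.03, density_cy5 = 0.02,
      colocalized_fraction = 0,
      fluor_count_distribution = c(0.85, 0.12, 0.03)
    )
  }
  density_cy3 <- density_cy3 %||% defaults$density_cy3
  density_cy5 <- density_cy5 %||% defaults$density_cy5
  colocalized_fraction <- colocalized_fraction %||% defaults$colocalized_fraction
  fluor_count_distribution <-
    fluor_count_distribution %||% defaults$fluor_count_distribution

  if (density_cy3 < 0 || density_cy5 < 0) abort("densities must be >= 0")
  if (colocalized_fraction < 0 || colocalized_fraction > 1) {
    abort("`colocalized_fraction` must lie in [0, 1]")
  }
  p <- fluor_count_distribution
  if (any(p < 0) || abs(sum(p) - 1) > 1e-8) {
    abort("`fluor_count_distribution` must be a probability vector summing to 1")
  }
  if (length(registration_offset) != 2 || any(abs(registration_offset) > 3)) {
    abort("`registration_offset` must be two components, each within 3 px")
  }
  if (bleach_rate <= 0) abort("`bleach_rate` must be positive")
  structure(
    list(
      condition = condition,
      density_cy3 = density_cy3, density_cy5 = density_cy5,
      colocalized_fraction = colocalized_fraction,
      fluor_count_distribution = p,
      bleach_rate = bleach_rate,
      registration_offset = as.numeric(registration_offset),
      unit_intensity = unit_intensity
    ),
    class = "condition_spec"
  )
}

#' EMCCD camera and optics model for rendering
#'
#' Parameters of the simple image-formation model used by [render_movie()]:
#' a pixel-integrated Gaussian point-spread function, a planar background,
#' Poisson shot noise scaled by the camera gain, and Gaussian read noise.
#'
#' @param psf_sigma Gaussian PSF standard deviation in px (must be positive).
#' @param background_offset Background level at the image origin, AU.
#' @param background_gradient Length-2 planar gradient `(per row, per col)`,
#'   AU/px.
#' @param read_noise_sd Gaussian read-noise standard deviation, AU.
#' @param gain Grayscale units per detected photon.
#' @param frame_interval Time between frames, seconds.
#' @return A `camera_model` list.
#' @export
camera_model <- function(psf_sigma = 1.2, background_offset = 500,
                         background_gradient = c(0.5, 0.3),
                         read_noise_sd = 10, gain = 1, frame_interval = 1) {
  if (psf_sigma <= 0) abort("`psf_sigma` must be positive")
  if (read_noise_sd < 0) abort("`read_noise_sd` must be >= 0")
  if (gain <= 0) abort("`gain` must be positive")
  structure(
    list(
      psf_sigma = psf_sigma, background_offset = background_offset,
      background_gradient = as.numeric(background_gradient),
      read_noise_sd = read_noise_sd, gain = gain,
      frame_interval = frame_interval
    ),
    class = "camera_model"
  )
}

draw_channel_spots <- function(n, channel, H, W, spec, n_frames,
                               frame_interval) {
  k_max <- length(spec$fluor_count_distribution)
  nf <- if (n > 0) {
    sample.int(k_max, n, replace = TRUE, prob = spec$fluor_count_distribution)
  } else {
    integer(0)
  }
  bleach <- lapply(nf, function(k) {
    t_bleach <- rexp(k, rate = spec$bleach_rate)
    sort(pmax(1L, as.integer(ceiling(t_bleach / frame_interval))))
  })
  tibble::tibble(
    spot_id = seq_len(n), channel = rep(channel, n),
    row = runif(n, 0, H) - 0.5, col = runif(n, 0, W) - 0.5,
    n_fluorophores = as.integer(nf),
    bleach_frames = bleach,
    unit_intensity = rep(spec$unit_intensity, n)
  )
}

#' Simulate ground-truth spot fields for both channels
#'
#' Places spots by a homogeneous Poisson process at each channel's density.
#' A fraction `colocalized_fraction` of Cy5 spots is then relocated to the
#' position of a randomly chosen Cy3 spot, displaced by the registration
#' offset, so the two channels share truly dual-labelled positions (the
#' physical picture of Cy3- and Cy5-ncAA encoded within one channel complex
#' or cluster). Per-spot fluorophore counts are drawn from the spec's count
#' distribution and per-fluorophore bleach times are i.i.d. exponential with
#' the spec's bleach rate, converted to frame indices (a bleach frame `b`
#' means the drop occurs at the transition into frame `b`, 0-based; frames
#' at or beyond `n_frames` are censored: the fluorophore outlives the movie).
#'
#' @param spec A [condition_spec()].
#' @param dim Field dimensions `c(H, W)` in px; both positive.
#' @param pixel_size Pixel size, µm/px.
#' @param n_frames Number of frames the movie will have.
#' @param frame_interval Frame interval, seconds.
#' @param seed Optional integer seed; the result is fully reproducible.
#' @return A list with class `spot_field`: tibbles `cy3` and `cy5`
#'   (`spot_id`, `channel`, `row`, `col` 0-based px, `n_fluorophores`,
#'   `bleach_frames` list-column, `unit_intensity`), tibble `pairs`
#'   (`cy3_id`, `cy5_id`) of truly colocalized spots, plus `dim`,
#'   `pixel_size`, and the `spec`.
#' @export
simulate_spot_field <- function(spec, dim = c(128, 128), pixel_size = 0.2,
                                n_frames = 100, frame_interval = 1,
                                seed = NULL) {
  stopifnot(inherits(spec, "condition_spec"))
  H <- dim[1]; W <- dim[2]
  if (H <= 0 || W <= 0) abort("field dimensions must be positive")
  if (!is.null(seed)) set.seed(seed)

  area_um2 <- H * W * pixel_size^2
  n3 <- rpois(1, spec$density_cy3 * area_um2)
  n5 <- rpois(1, spec$density_cy5 * area_um2)
  cy3 <- draw_channel_spots(n3, "Cy3", H, W, spec, n_frames, frame_interval)
  cy5 <- draw_channel_spots(n5, "Cy5", H, W, spec, n_frames, frame_interval)

  pairs <- tibble::tibble(cy3_id = integer(0), cy5_id = integer(0))
  if (n5 > 0 && n3 > 0 && spec$colocalized_fraction > 0) {
    is_coloc <- runif(n5) < spec$colocalized_fraction
    if (any(is_coloc)) {
      partner <- sample.int(n3, sum(is_coloc), replace = TRUE)
      idx <- which(is_coloc)
      cy5$row[idx] <- cy3$row[partner] + spec$registration_offset[1]
      cy5$col[idx] <- cy3$col[partner] + spec$registration_offset[2]
      # partners pushed out of the field are re-drawn uniformly (stay CSR)
      oob <- cy5$row[idx] < -0.5 | cy5$row[idx] > H - 0.5 |
        cy5$col[idx] < -0.5 | cy5$col[idx] > W - 0.5
      if (any(oob)) {
        cy5$row[idx[oob]] <- runif(sum(oob), 0, H) - 0.5
        cy5$col[idx[oob]] <- runif(sum(oob), 0, W) - 0.5
      }
      keep <- !oob
      pairs <- tibble::tibble(
        cy3_id = partner[keep],
        cy5_id = idx[keep]
      )
    }
  }
  structure(
    list(
      cy3 = cy3, cy5 = cy5, pairs = pairs,
      dim = c(H, W), pixel_size = pixel_size, n_frames = n_frames,
      frame_interval = frame_interval, spec = spec
    ),
    class = "spot_field"
  )
}

#' Simulate a single photobleaching intensity trace
#'
#' The ideal trace of one diffraction-limited spot: it starts at
#' `n_fluorophores * unit_intensity`, drops by `unit_intensity` at each
#' bleach frame, and sits at baseline 0 after the last fluorophore has
#' bleached. Gaussian noise of standard deviation `noise_sd` is added.
#'
#' @param n_fluorophores Number of fluorophores (>= 0).
#' @param unit_intensity Intensity contributed by one fluorophore, AU.
#' @param bleach_frames Frame indices (0-based) at which each fluorophore
#'   bleaches; the drop happens at the transition into that frame. Defaults
#'   to i.i.d. exponential draws at `bleach_rate`.
#' @param n_frames Trace length in frames (>= 1).
#' @param noise_sd Gaussian noise standard deviation, AU (>= 0).
#' @param bleach_rate Bleach rate (1/frame) used when `bleach_frames` is NULL.
#' @param seed Optional seed.
#' @return A list with `trace` (tibble `frame` 0-based, `intensity`),
#'   `true_steps` (sorted bleach frames that fall inside the movie) and
#'   `ideal` (the noise-free trace).
#' @export
simulate_bleach_trace <- function(n_fluorophores, unit_intensity = 3000,
                                  bleach_frames = NULL, n_frames = 100,
                                  noise_sd = 0, bleach_rate = 0.03,
                                  seed = NULL) {
  if (n_frames < 1) abort("`n_frames` must be >= 1")
  if (noise_sd < 0) abort("`noise_sd` must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(bleach_frames)) {
    bleach_frames <- pmax(1L, as.integer(ceiling(rexp(n_fluorophores,
      rate = bleach_rate
    ))))
  }
  if (length(bleach_frames) != n_fluorophores) {
    abort("`bleach_frames` must have one entry per fluorophore")
  }
  bleach_frames <- sort(bleach_frames)
  t <- seq_len(n_frames) - 1L
  live <- vapply(t, function(tt) sum(bleach_frames > tt), numeric(1))
  ideal <- live * unit_intensity
  values <- ideal + if (noise_sd > 0) rnorm(n_frames, 0, noise_sd) else 0
  list(
    trace = tibble::tibble(frame = t, intensity = values),
    true_steps = bleach_frames[bleach_frames <= n_frames - 1L &
      bleach_frames >= 1L],
    ideal = ideal
  )
}

# Pixel-integrated Gaussian mass of a unit point source at (r, c) over the
# window rows x cols (0-based pixel centers; pixel i spans [i-.5, i+.5]).
psf_patch <- function(r, c, rows, cols, sigma) {
  mr <- pnorm(rows + 0.5, r, sigma) - pnorm(rows - 0.5, r, sigma)
  mc <- pnorm(cols + 0.5, c, sigma) - pnorm(cols - 0.5, c, sigma)
  outer(mr, mc)
}

background_plane <- function(H, W, camera) {
  g <- camera$background_gradient
  camera$background_offset +
    outer((seq_len(H) - 1) * g[1], rep(1, W)) +
    outer(rep(1, H), (seq_len(W) - 1) * g[2])
}

#' Render one channel of a spot field into an image stack
#'
#' Each live fluorophore contributes a pixel-integrated 2-D Gaussian of its
#' unit intensity at the camera's PSF width; the background is a planar
#' offset plus gradient; per-pixel noise is Poisson shot noise scaled by the
#' camera gain plus Gaussian read noise. Output is clipped to the 16-bit
#' range; if any pixel saturates, the stack carries a `saturated = TRUE`
#' attribute.
#'
#' @param field A `spot_field` from [simulate_spot_field()].
#' @param camera A [camera_model()].
#' @param channel `"Cy3"` or `"Cy5"`.
#' @param n_frames Number of frames to render (default the field's).
#' @param seed Optional seed; a fixed seed gives a bit-identical stack.
#' @param noise If `FALSE`, render the noise-free expectation (useful for
#'   ground-truth checks).
#' @return An [image_stack()].
#' @export
render_movie <- function(field, camera, channel = c("Cy3", "Cy5"),
                         n_frames = NULL, seed = NULL, noise = TRUE) {
  stopifnot(inherits(field, "spot_field"), inherits(camera, "camera_model"))
  channel <- match.arg(channel)
  H <- field$dim[1]; W <- field$dim[2]
  if (camera$psf_sigma >= min(H, W)) {
    abort("`psf_sigma` must be smaller than the field dimensions")
  }
  n_frames <- n_frames %||% field$n_frames
  if (!is.null(seed)) set.seed(seed)

  spots <- if (channel == "Cy3") field$cy3 else field$cy5
  bg <- background_plane(H, W, camera)
  clean <- array(rep(bg, each = n_frames), dim = c(n_frames, H, W))

  half <- ceiling(4 * camera$psf_sigma) + 1
  t0 <- seq_len(n_frames) - 1L
  for (s in seq_len(nrow(spots))) {
    r <- spots$row[s]; c <- spots$col[s]
    rows <- max(0, floor(r - half)):min(H - 1, ceiling(r + half))
    cols <- max(0, floor(c - half)):min(W - 1, ceiling(c + half))
    if (!length(rows) || !length(cols)) next
    patch <- psf_patch(r, c, rows, cols, camera$psf_sigma) *
      spots$unit_intensity[s]
    bf <- spots$bleach_frames[[s]]
    live <- vapply(t0, function(tt) sum(bf > tt), numeric(1))
    active <- which(live > 0)
    for (t in active) {
      clean[t, rows + 1, cols + 1] <- clean[t, rows + 1, cols + 1] +
        live[t] * patch
    }
  }

  if (noise) {
    photons <- clean / camera$gain
    out <- array(
      rpois(length(photons), lambda = photons) * camera$gain +
        rnorm(length(photons), 0, camera$read_noise_sd),
      dim = dim(clean)
    )
  } else {
    out <- clean
  }
  saturated <- any(out > 65535)
  out <- round(pmin(pmax(out, 0), 65535))
  st <- image_stack(out,
    pixel_size = field$pixel_size,
    frame_interval = camera$frame_interval, channel = channel
  )
  attr(st, "saturated") <- saturated
  st
}

serialize_frames <- function(x) {
  vapply(x, function(v) paste(v, collapse = ";"), character(1))
}

#' Write a complete synthetic two-channel dataset to disk
#'
#' Renders the Cy3 and Cy5 movies for one condition and writes them as
#' multi-page 16-bit TIFFs together with ground-truth CSV tables
#' (`spots.csv`, `traces.csv`, `pairs.csv`) and a JSON metadata file. The
#' same seed always produces identical files.
#'
#' @inheritParams simulate_spot_field
#' @param camera A [camera_model()].
#' @param out_dir Output directory (created if missing).
#' @param seed Master seed; stage-specific child seeds are derived from it.
#' @return Invisibly, a list with the `spot_field` and the file paths.
#' @export
make_condition_dataset <- function(spec, camera = camera_model(),
                                   dim = c(128, 128), pixel_size = 0.2,
                                   n_frames = 100, out_dir, seed = 1) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(paste0("cannot create output directory: ", out_dir))
  }
  field <- simulate_spot_field(spec, dim, pixel_size,
    n_frames = n_frames,
    frame_interval = camera$frame_interval, seed = child_seed(seed, 1)
  )
  cy3 <- render_movie(field, camera, "Cy3", seed = child_seed(seed, 2))
  cy5 <- render_movie(field, camera, "Cy5", seed = child_seed(seed, 3))

  paths <- list(
    cy3 = file.path(out_dir, "cy3.tif"),
    cy5 = file.path(out_dir, "cy5.tif"),
    spots = file.path(out_dir, "spots.csv"),
    traces = file.path(out_dir, "traces.csv"),
    pairs = file.path(out_dir, "pairs.csv"),
    metadata = file.path(out_dir, "metadata.json")
  )
  write_stack(cy3, paths$cy3)
  write_stack(cy5, paths$cy5)

  spots <- dplyr::bind_rows(field$cy3, field$cy5)
  spots$bleach_frames <- serialize_frames(spots$bleach_frames)
  utils::write.csv(spots, paths$spots, row.names = FALSE)

  traces <- dplyr::bind_rows(field$cy3, field$cy5) |>
    dplyr::mutate(
      n_steps_in_movie = vapply(
        .data$bleach_frames,
        function(b) sum(b >= 1 & b <= n_frames - 1), numeric(1)
      ),
      bleach_frames = serialize_frames(.data$bleach_frames)
    ) |>
    dplyr::select(
      "spot_id", "channel", "n_fluorophores",
      "n_steps_in_movie", "bleach_frames"
    )
  utils::write.csv(traces, paths$traces, row.names = FALSE)
  utils::write.csv(field$pairs, paths$pairs, row.names = FALSE)

  meta <- list(
    condition = spec$condition, pixel_size = pixel_size,
    frame_interval = camera$frame_interval, n_frames = n_frames,
    dim = dim, seed = seed,
    density_cy3 = spec$density_cy3, density_cy5 = spec$density_cy5,
    colocalized_fraction = spec$colocalized_fraction,
    fluor_count_distribution = spec$fluor_count_distribution,
    bleach_rate = spec$bleach_rate,
    registration_offset = spec$registration_offset,
    unit_intensity = spec$unit_intensity
  )
  jsonlite::write_json(meta, paths$metadata, auto_unbox = TRUE, digits = NA)
  invisible(list(field = field, paths = paths))
}
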
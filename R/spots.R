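#' Spot detection parameters
#'
#' Detection thresholds are expressed in post-subtraction grayscale units,
#' the scale on which single-molecule spot intensities are conventionally
#' gated (Cy3 around 150-190 units, Cy5 around 130-150 units on typical
#' EMCCD settings; the preset midpoints are 170 and 140).
#'
#' @param intensity_threshold Pixel threshold, AU (> 0).
#' @param area_min,area_max Component area bounds in px².
#' @param aoi_size AOI window edge in px; odd and >= 3 (default 7).
#' @param min_separation Minimum centroid separation in px; closer detections
#'   are merged, keeping the brightest.
#' @param split_merged Split connected components containing several
#'   regional intensity maxima at least `split_sep` apart into one
#'   candidate per maximum (default `TRUE`). At realistic densities a
#'   noticeable share of genuine spots sit close enough that their
#'   above-threshold disks touch; without splitting such pairs are counted
#'   once and the number density is biased low.
#' @param split_sep Minimum separation (px) between regional maxima treated
#'   as distinct spots when splitting. The default of 3 px is the practical
#'   two-point resolution of the ~1.2 px PSF: closer pairs do not produce
#'   separate intensity maxima and cannot be told apart.
#' @return A `detection_params` list.
#' @export
detection_params <- function(intensity_threshold = 170, area_min = 2,
                             area_max = 80, aoi_size = 7,
                             min_separation = 4, split_merged = TRUE,
                             split_sep = 3) {
  if (intensity_threshold <= 0) abort("`intensity_threshold` must be > 0")
  if (aoi_size < 3 || aoi_size %% 2 == 0) abort("`aoi_size` must be odd, >= 3")
  if (area_min > area_max) abort("`area_min` must be <= `area_max`")
  structure(
    list(
      intensity_threshold = intensity_threshold,
      area_min = area_min, area_max = area_max,
      aoi_size = aoi_size, min_separation = min_separation,
      split_merged = split_merged, split_sep = split_sep
    ),
    class = "detection_params"
  )
}

#' Default threshold presets per channel
#' @param channel `"Cy3"` or `"Cy5"`.
#' @return The preset intensity threshold in grayscale units.
#' @export
default_threshold <- function(channel = c("Cy3", "Cy5")) {
  channel <- match.arg(channel)
  if (channel == "Cy3") 170 else 140
}

#' Detect fluorescent spots in a background-subtracted first frame
#'
#' Pixels at or above the intensity threshold are grouped into 8-connected
#' components; components with area inside `[area_min, area_max]` become
#' candidate spots located at their intensity-weighted centroid rounded to
#' the nearest pixel. Candidates whose centroids fall closer than
#' `min_separation` (Euclidean) are merged and only the brightest (highest
#' peak intensity) survives. A fixed odd-sized square AOI (area of interest,
#' default 7x7) is anchored at each surviving centroid; AOIs whose window
#' would leave the frame are dropped. The result is ordered by `(row, col)`.
#'
#' @param frame A background-subtracted 2-D matrix (the first movie frame).
#' @param params A [detection_params()].
#' @param channel Channel label attached to the AOIs.
#' @return A tibble with columns `id`, `channel`, `row`, `col` (0-based
#'   center pixel), `area` (px²), `peak` and `total` (AU).
#' @export
detect_spots <- function(frame, params = detection_params(),
                         channel = "Cy3") {
  H <- nrow(frame); W <- ncol(frame)
  empty <- tibble::tibble(
    id = integer(0), channel = character(0), row = integer(0),
    col = integer(0), area = integer(0), peak = numeric(0),
    total = numeric(0)
  )
  cand <- spot_candidates(frame, params)
  if (nrow(cand) == 0) return(empty)

  # merge near-duplicates: brightest first, ties broken by (row, col)
  ord <- order(-cand$peak, cand$row, cand$col)
  cand <- cand[ord, ]
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    kept <- which(keep)
    if (!length(kept)) {
      keep[i] <- TRUE
      next
    }
    d2 <- (cand$row[kept] - cand$row[i])^2 + (cand$col[kept] - cand$col[i])^2
    keep[i] <- all(d2 >= params$min_separation^2)
  }
  cand <- cand[keep, ]

  half <- (params$aoi_size - 1) / 2
  inside <- cand$row - half >= 0 & cand$row + half <= H - 1 &
    cand$col - half >= 0 & cand$col + half <= W - 1
  cand <- cand[inside, ]
  cand <- cand[order(cand$row, cand$col), ]
  tibble::tibble(
    id = seq_len(nrow(cand)), channel = rep(channel, nrow(cand)),
    row = cand$row, col = cand$col, area = cand$area,
    peak = cand$peak, total = cand$total
  )
}

# Thresholded 8-connected components with area in range, located at the
# intensity-weighted centroid rounded to the nearest pixel. Shared by
# detect_spots() (which additionally merges near-duplicates and clips AOI
# windows) and count_spots().
spot_candidates <- function(frame, params = detection_params()) {
  if (!is.matrix(frame)) abort("`frame` must be a 2-D matrix")
  H <- nrow(frame)
  mask <- frame >= params$intensity_threshold
  lab <- cpp_label8(mask)
  n_comp <- max(lab)
  if (n_comp == 0) {
    return(tibble::tibble(
      row = integer(0), col = integer(0), area = integer(0),
      peak = numeric(0), total = numeric(0)
    ))
  }
  idx <- which(lab > 0)
  comp <- lab[idx]
  ri <- (idx - 1) %% H      # 0-based row
  ci <- (idx - 1) %/% H     # 0-based col
  w <- frame[idx]

  if (params$split_merged) {
    is_max <- local_maxima(frame)[idx]
    comp <- split_components(comp, ri, ci, w, is_max, params$split_sep)
    n_comp <- max(comp)
  }

  area <- tabulate(comp, n_comp)
  tot <- as.numeric(rowsum(w, comp))
  wr <- as.numeric(rowsum(w * ri, comp)) / tot
  wc <- as.numeric(rowsum(w * ci, comp)) / tot
  peak <- vapply(split(w, comp), max, numeric(1))
  cand <- tibble::tibble(
    row = as.integer(round(wr)), col = as.integer(round(wc)),
    area = as.integer(area), peak = as.numeric(peak), total = tot
  )
  cand <- cand[cand$area >= params$area_min & cand$area <= params$area_max, ]
  cand[order(cand$row, cand$col), ]
}

# TRUE where a pixel is >= all of its 8 neighbours (borders padded -Inf).
local_maxima <- function(frame) {
  H <- nrow(frame); W <- ncol(frame)
  pad <- matrix(-Inf, H + 2, W + 2)
  pad[2:(H + 1), 2:(W + 1)] <- frame
  res <- matrix(TRUE, H, W)
  for (di in -1:1) {
    for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      res <- res & frame >= pad[(2 + di):(H + 1 + di), (2 + dj):(W + 1 + dj)]
    }
  }
  res
}

# Re-label component pixels so that a component holding several regional
# maxima separated by at least min_sep becomes one label per maximum, pixels
# assigned to the nearest selected maximum. Returns new 1..K labels.
split_components <- function(comp, ri, ci, w, is_max, min_sep) {
  new_comp <- integer(length(comp))
  next_lab <- 0L
  for (k in seq_len(max(comp))) {
    members <- which(comp == k)
    sel <- integer(0)
    mx <- members[is_max[members]]
    mx <- mx[order(-w[mx], ri[mx], ci[mx])]
    for (m in mx) {
      if (!length(sel) ||
        all((ri[sel] - ri[m])^2 + (ci[sel] - ci[m])^2 >= min_sep^2)) {
        sel <- c(sel, m)
      }
    }
    if (length(sel) <= 1) {
      next_lab <- next_lab + 1L
      new_comp[members] <- next_lab
    } else {
      d2 <- outer(ri[members], ri[sel], "-")^2 +
        outer(ci[members], ci[sel], "-")^2
      assign <- max.col(-d2, ties.method = "first")
      new_comp[members] <- next_lab + assign
      next_lab <- next_lab + length(sel)
    }
  }
  new_comp
}

#' Count above-threshold spots for density estimation
#'
#' Counts every thresholded component with area in range, before the AOI
#' stages of [detect_spots()] (duplicate merging and window clipping):
#' number density is a property of the whole field, whereas AOIs must
#' additionally fit a full window inside the frame and be non-duplicated
#' for trace extraction, which discards a border- and density-dependent
#' share of genuine spots.
#'
#' @inheritParams detect_spots
#' @return Integer spot count.
#' @export
count_spots <- function(frame, params = detection_params()) {
  nrow(spot_candidates(frame, params))
}

#' Spot number density per µm² of membrane
#'
#' @param aois An AOI tibble from [detect_spots()], or a spot count.
#' @param dim Frame dimensions `c(H, W)` in px; both positive.
#' @param pixel_size Pixel size, µm/px (> 0).
#' @return Spots per µm².
#' @export
spot_density <- function(aois, dim, pixel_size) {
  n <- if (is.data.frame(aois)) nrow(aois) else as.numeric(aois)
  if (any(dim <= 0)) abort("frame dimensions must be positive")
  if (pixel_size <= 0) abort("`pixel_size` must be positive")
  n / (dim[1] * dim[2] * pixel_size^2)
}

#' Overlap-corrected spot density estimate
#'
#' Even with maxima-based splitting, two spots closer than the two-point
#' resolution of the PSF produce a single intensity maximum and are counted
#' once. For spots placed by a homogeneous Poisson process the expected
#' observed count is `E[N] = n - n^2 * pi * d^2 / (2 A)` to first order in
#' the overlap (each unresolvable pair within distance `d` costs one
#' count). Inverting this quadratic de-biases the count:
#' `n_hat = (1 - sqrt(1 - 4 c N)) / (2 c)` with `c = pi d^2 / (2 A)`.
#'
#' @param n_obs Observed spot count (e.g. from [count_spots()]).
#' @param dim Frame dimensions `c(H, W)` in px.
#' @param pixel_size Pixel size, µm/px.
#' @param resolution_px Two-point resolution distance `d` in px; use the
#'   detection `split_sep` (default 3).
#' @return Estimated density in spots/µm².
#' @export
density_estimate <- function(n_obs, dim, pixel_size, resolution_px = 3) {
  A <- dim[1] * dim[2]
  cc <- pi * resolution_px^2 / (2 * A)
  disc <- 1 - 4 * cc * n_obs
  n_hat <- if (disc > 0) (1 - sqrt(disc)) / (2 * cc) else 1 / (2 * cc)
  spot_density(n_hat, dim, pixel_size)
}

#' Hierarchical density summary across movies and oocytes
#'
#' Per-movie densities are averaged within each oocyte, then pooled across
#' oocytes as mean ± s.e.m., matching the per-movie / per-oocyte / pooled
#' reporting convention of single-molecule membrane imaging.
#'
#' @param densities A tibble with columns `oocyte`, `movie`, `density`.
#' @return A one-row tibble: `mean`, `sem`, `n_oocytes`.
#' @export
density_summary <- function(densities) {
  stopifnot(all(c("oocyte", "density") %in% names(densities)))
  mean_sem(densities$density, group = densities$oocyte) |>
    dplyr::rename(n_oocytes = "n_groups")
}
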
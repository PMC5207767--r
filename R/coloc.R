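#' Map Cy5 AOI coordinates onto the Cy3 field
#'
#' Applies the (integer or fractional) registration offset that relates the
#' two camera fields. Mapped points whose centers leave the frame are
#' flagged `in_frame = FALSE` and are excluded from the colocalization
#' denominator.
#'
#' @param aois Tibble with `row`, `col` (0-based px).
#' @param offset `(d_row, d_col)` in px; finite.
#' @param dim Frame dimensions `c(H, W)`.
#' @return The tibble with translated `row`, `col` and an `in_frame` flag.
#' @export
map_aois <- function(aois, offset = c(0, 0), dim) {
  if (length(offset) != 2 || !all(is.finite(offset))) {
    abort("`offset` must be two finite components")
  }
  out <- aois
  out$row <- aois$row + offset[1]
  out$col <- aois$col + offset[2]
  out$in_frame <- out$row >= 0 & out$row <= dim[1] - 1 &
    out$col >= 0 & out$col <= dim[2] - 1
  out
}

#' Estimate the inter-channel registration offset from spot maps
#'
#' Scans integer candidate offsets within `max_shift` and returns the
#' registration offset `d` (Cy5 field relative to Cy3, so `cy5 ≈ cy3 + d`)
#' that maximizes the number of Cy5 spots with a Cy3 spot within
#' `match_radius` (Chebyshev) after un-shifting. Ties favour the smallest
#' offset magnitude, then row/col order, so the estimate is deterministic.
#'
#' @param cy5_aois,cy3_aois AOI tibbles with `row`, `col`.
#' @param max_shift Search half-width in px.
#' @param match_radius Match window half-width in px.
#' @return Integer `c(d_row, d_col)`: the Cy5-relative-to-Cy3 offset; map
#'   Cy5 onto the Cy3 field with `map_aois(cy5, -offset, dim)`.
#' @export
estimate_offset <- function(cy5_aois, cy3_aois, max_shift = 3,
                            match_radius = 1) {
  shifts <- expand.grid(
    d_row = -max_shift:max_shift,
    d_col = -max_shift:max_shift
  )
  score <- vapply(seq_len(nrow(shifts)), function(i) {
    n_matched(
      cy5_aois$row - shifts$d_row[i], cy5_aois$col - shifts$d_col[i],
      cy3_aois$row, cy3_aois$col, match_radius
    )
  }, numeric(1))
  ord <- order(-score, shifts$d_row^2 + shifts$d_col^2,
    shifts$d_row, shifts$d_col)
  as.numeric(shifts[ord[1], ])
}

n_matched <- function(r5, c5, r3, c3, tol) {
  if (!length(r5) || !length(r3)) return(0)
  sum(vapply(seq_along(r5), function(i) {
    any(pmax(abs(r3 - r5[i]), abs(c3 - c5[i])) <= tol)
  }, logical(1)))
}

#' Colocalized fraction of Cy5 spots
#'
#' A mapped Cy5 spot counts as colocalized when at least one Cy3 AOI center
#' lies within Chebyshev (square-window) distance `tolerance` — the square
#' metric matches the square AOI windows, and the default of 2 px covers the
#' residual 1-2 px mapping error between fields. One Cy3 spot may validate
#' several Cy5 spots; there is no exclusive matching and no intensity
#' criterion on the Cy3 partner.
#'
#' @param cy5_mapped Cy5 AOIs already mapped by [map_aois()] (rows with
#'   `in_frame == FALSE` are dropped from the denominator).
#' @param cy3_aois Cy3 AOI tibble.
#' @param tolerance Match distance in px (>= 0).
#' @return A one-row tibble: `n_cy5`, `n_coloc`, `fraction` (`NA` with a
#'   warning when no Cy5 spot is in frame).
#' @export
colocalized_fraction <- function(cy5_mapped, cy3_aois, tolerance = 2) {
  if (tolerance < 0) abort("`tolerance` must be >= 0")
  keep <- if ("in_frame" %in% names(cy5_mapped)) {
    cy5_mapped$in_frame
  } else {
    rep(TRUE, nrow(cy5_mapped))
  }
  r5 <- cy5_mapped$row[keep]
  c5 <- cy5_mapped$col[keep]
  n5 <- length(r5)
  if (n5 == 0) {
    warn("no in-frame Cy5 spots; colocalized fraction undefined")
    return(tibble::tibble(n_cy5 = 0L, n_coloc = 0L, fraction = NA_real_))
  }
  nc <- n_matched(r5, c5, cy3_aois$row, cy3_aois$col, tolerance)
  tibble::tibble(
    n_cy5 = n5, n_coloc = as.integer(nc),
    fraction = nc / n5
  )
}

#' Rotate spot coordinates 90 degrees about the image center
#'
#' The random-colocalization null: one channel's spot pattern is rotated a
#' quarter turn about the center before re-scoring overlap, destroying true
#' pairings while preserving the pattern's density and internal geometry
#' (the rotation is an isometry). For non-square frames the rotation acts on
#' the largest centered square; points outside it are dropped.
#'
#' @param aois Tibble with `row`, `col` (0-based px).
#' @param dim Frame dimensions `c(H, W)`.
#' @return The tibble with rotated coordinates (possibly fewer rows).
#' @export
rotation_null <- function(aois, dim) {
  H <- dim[1]; W <- dim[2]
  s <- min(H, W)
  r0 <- (H - s) / 2
  c0 <- (W - s) / 2
  r <- aois$row - r0
  c <- aois$col - c0
  inside <- r >= 0 & r <= s - 1 & c >= 0 & c <= s - 1
  out <- aois[inside, , drop = FALSE]
  rr <- r[inside]
  cc <- c[inside]
  out$row <- cc + r0
  out$col <- (s - 1 - rr) + c0
  out
}

#' Expected colocalized fraction under complete spatial randomness
#'
#' For a Cy3 channel that is a homogeneous Poisson process of density
#' `lambda` (spots/µm²), the chance that an unrelated Cy5 spot has at least
#' one Cy3 center within Chebyshev distance `tolerance` px is
#' `1 - exp(-lambda * ((2 * tolerance + 1) * pixel_size)^2)`.
#'
#' @param lambda Cy3 density, spots/µm².
#' @param tolerance Match distance, px.
#' @param pixel_size Pixel size, µm/px.
#' @return Expected chance-colocalization fraction.
#' @export
csr_expected_fraction <- function(lambda, tolerance = 2, pixel_size = 0.2) {
  1 - exp(-lambda * (2 * tolerance + 1)^2 * pixel_size^2)
}

#' Full colocalization analysis of one movie
#'
#' Maps the Cy5 AOIs onto the Cy3 field, scores the observed colocalized
#' fraction, and scores the 90-degree rotation null on the same spot sets.
#'
#' @param cy3_aois,cy5_aois AOI tibbles from [detect_spots()].
#' @param dim Frame dimensions `c(H, W)`.
#' @param offset Registration offset `(d_row, d_col)` of the Cy5 field
#'   relative to Cy3; `NULL` to estimate it with [estimate_offset()].
#' @param tolerance Match distance in px.
#' @return A `coloc_result`: one-row tibble with `n_cy5`, `n_coloc`,
#'   `fraction`, `null_n_cy5`, `null_n_coloc`, `null_fraction`,
#'   `corrected_fraction` (observed minus null) and the offset used.
#' @export
coloc_analysis <- function(cy3_aois, cy5_aois, dim, offset = NULL,
                           tolerance = 2) {
  offset <- offset %||% estimate_offset(cy5_aois, cy3_aois)
  mapped <- map_aois(cy5_aois, -offset, dim)
  obs <- colocalized_fraction(mapped, cy3_aois, tolerance)
  rot <- rotation_null(mapped[mapped$in_frame, , drop = FALSE], dim)
  nul <- colocalized_fraction(rot, cy3_aois, tolerance)
  out <- tibble::tibble(
    n_cy5 = obs$n_cy5, n_coloc = obs$n_coloc, fraction = obs$fraction,
    null_n_cy5 = nul$n_cy5, null_n_coloc = nul$n_coloc,
    null_fraction = nul$fraction,
    corrected_fraction = obs$fraction - nul$fraction,
    d_row = offset[1], d_col = offset[2]
  )
  class(out) <- c("coloc_result", class(out))
  out
}

#' Pool per-movie colocalization across oocytes
#'
#' Per-movie fractions are averaged within oocytes and pooled across
#' oocytes as mean ± s.e.m., for the observed, null and null-subtracted
#' fractions.
#'
#' @param results Tibble with columns `oocyte`, `fraction`, `null_fraction`
#'   (one row per movie), e.g. stacked [coloc_analysis()] rows.
#' @return A tibble with one row per statistic: `statistic`, `mean`, `sem`,
#'   `n_oocytes`.
#' @export
coloc_summary <- function(results) {
  stopifnot(all(c("oocyte", "fraction", "null_fraction") %in% names(results)))
  stat <- function(v, name) {
    ok <- !is.na(v)
    dplyr::mutate(
      mean_sem(v[ok], group = results$oocyte[ok]),
      statistic = name, .before = 1
    )
  }
  dplyr::bind_rows(
    stat(results$fraction, "observed"),
    stat(results$null_fraction, "null"),
    stat(results$fraction - results$null_fraction, "corrected")
  ) |>
    dplyr::rename(n_oocytes = "n_groups")
}
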
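#' Molar extinction coefficients used for acylation quantification
#'
#' 260 nm coefficient for the THG73 suppressor tRNA and dye-peak
#' coefficients for Cy3 (550 nm) and Cy5 (650 nm), all in 1/(M cm). LD550's
#' coefficient is not published (vendor structure withheld) and must be
#' supplied by the user.
#' @export
extinction_coefficients <- c(THG73 = 696100, Cy3 = 150000, Cy5 = 250000)

#' tRNA ligation (acylation) efficiency from absorbances
#'
#' The fraction of tRNA molecules carrying a dye, from the Lambert-Beer law:
#' `efficiency (%) = A_dye * eps_rna / (A_rna * eps_dye) * 100`. A value
#' above 100% is allowed (measurement noise at 1:1 stoichiometry) but
#' flagged via the `"flagged"` attribute. The operation is homogeneous of
#' degree zero: rescaling both absorbances together (e.g. a serial dilution)
#' leaves it unchanged.
#'
#' @param A_rna Absorbance at 260 nm (> 0).
#' @param A_dye Absorbance at the dye peak (550 nm for Cy3/LD550, 650 nm for
#'   Cy5).
#' @param dye `"Cy3"`, `"Cy5"` or `"LD550"`.
#' @param eps_dye Dye extinction coefficient, 1/(M cm); required for LD550,
#'   defaulted from [extinction_coefficients] otherwise.
#' @param eps_rna tRNA extinction coefficient at 260 nm, 1/(M cm).
#' @return Efficiency in percent (vectorized over absorbances).
#' @export
ligation_efficiency <- function(A_rna, A_dye, dye = c("Cy3", "Cy5", "LD550"),
                                eps_dye = NULL,
                                eps_rna = extinction_coefficients[["THG73"]]) {
  dye <- match.arg(dye)
  if (is.null(eps_dye)) {
    if (dye == "LD550") {
      abort("LD550 has no published extinction coefficient; supply `eps_dye`")
    }
    eps_dye <- extinction_coefficients[[dye]]
  }
  if (any(A_rna <= 0)) abort("`A_rna` must be positive")
  if (any(A_dye < 0) || any(c(eps_dye, eps_rna) <= 0)) {
    abort("absorbances must be >= 0 and extinction coefficients > 0")
  }
  eff <- A_dye * eps_rna / (A_rna * eps_dye) * 100
  attr(eff, "flagged") <- eff > 100
  eff
}

#' Signal as a percentage of a positive control
#'
#' @param signal,control Mean signals (same units); `control` > 0.
#' @param digits Optional rounding for display (e.g. `0` for nearest
#'   percent); full precision is returned when `NULL`.
#' @return `100 * signal / control`, in percent.
#' @export
percent_of_control <- function(signal, control, digits = NULL) {
  if (any(control <= 0)) abort("`control` must be positive")
  out <- 100 * signal / control
  if (!is.null(digits)) out <- round(out, digits)
  out
}

#' Fold change of test currents over a background control
#'
#' `mean(test) / mean(background)`, with the standard error propagated by
#' the delta method for a ratio of independent means:
#' `sem = fold * sqrt(sem_t^2/mean_t^2 + sem_b^2/mean_b^2)`.
#'
#' @param test,background Per-oocyte current amplitudes (µA); non-empty,
#'   background mean > 0.
#' @return A one-row tibble: `fold`, `sem`, `n_test`, `n_background`.
#' @export
fold_over_background <- function(test, background) {
  if (!length(test) || !length(background)) abort("groups must be non-empty")
  mb <- mean(background)
  if (mb <= 0) abort("background mean must be positive")
  mt <- mean(test)
  se_t <- if (length(test) > 1) sd(test) / sqrt(length(test)) else 0
  se_b <- if (length(background) > 1) {
    sd(background) / sqrt(length(background))
  } else {
    0
  }
  fold <- mt / mb
  tibble::tibble(
    fold = fold,
    sem = abs(fold) * sqrt((se_t / mt)^2 + (se_b / mb)^2),
    n_test = length(test), n_background = length(background)
  )
}

#' Time for a current to decay to a fraction of its peak
#'
#' Locates the peak (maximum absolute current at or after the stimulus
#' onset) and returns the time from the peak to the first crossing of
#' `fraction * |I_peak|`, linearly interpolating between samples. For an
#' ideal exponential decay with time constant tau and `fraction = 0.1` the
#' answer is `tau * log(10)`. Amplitude rescaling of the trace leaves the
#' result unchanged.
#'
#' @param trace A tibble/data frame with columns `time_ms` and `current_uA`
#'   (uniform sampling), or a numeric current vector with `time_ms` supplied
#'   separately.
#' @param fraction Decay fraction (default 0.1, i.e. to 10% of peak).
#' @param onset_index First sample (1-based) eligible to be the peak.
#' @param time_ms Sample times when `trace` is a bare vector.
#' @return Decay time in ms, or `NA` (with a warning) when the trace never
#'   reaches the fraction.
#' @export
decay_time_to_fraction <- function(trace, fraction = 0.1, onset_index = 1,
                                   time_ms = NULL) {
  if (is.data.frame(trace)) {
    time_ms <- trace$time_ms
    current <- trace$current_uA
  } else {
    current <- trace
    if (is.null(time_ms)) time_ms <- seq_along(current) - 1
  }
  a <- abs(current)
  n <- length(a)
  if (onset_index < 1 || onset_index > n) abort("`onset_index` out of range")
  ip <- onset_index - 1 + which.max(a[onset_index:n])
  target <- fraction * a[ip]
  below <- which(a[ip:n] <= target)
  if (!length(below)) {
    warn("trace never decays to the requested fraction of its peak")
    return(NA_real_)
  }
  j <- ip - 1 + below[1]
  if (j == ip) return(0)
  # linear interpolation between the bracketing samples
  t_cross <- time_ms[j - 1] +
    (time_ms[j] - time_ms[j - 1]) * (a[j - 1] - target) / (a[j - 1] - a[j])
  t_cross - time_ms[ip]
}

#' Two-sample equal-variance t-test (closed form)
#'
#' Student's t-test, two-tailed, pooled variance, as used for all group
#' comparisons in this pipeline: `df = n_a + n_b - 2`. The degenerate case
#' of zero pooled variance returns `t = 0, p = 1` for equal means and is
#' flagged (`degenerate = TRUE`) with `p = 0` for unequal means.
#'
#' @param a,b Numeric vectors of per-unit (typically per-oocyte) values,
#'   each of length >= 2.
#' @return A one-row tibble: `t`, `df`, `p`, `mean_a`, `mean_b`,
#'   `degenerate`.
#' @export
two_sample_ttest <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2) abort("both samples need at least 2 values")
  df <- na + nb - 2
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / df
  ma <- mean(a); mb <- mean(b)
  if (sp2 == 0) {
    if (ma == mb) {
      return(tibble::tibble(
        t = 0, df = df, p = 1, mean_a = ma, mean_b = mb, degenerate = FALSE
      ))
    }
    return(tibble::tibble(
      t = sign(ma - mb) * Inf, df = df, p = 0, mean_a = ma, mean_b = mb,
      degenerate = TRUE
    ))
  }
  t <- (ma - mb) / sqrt(sp2 * (1 / na + 1 / nb))
  tibble::tibble(
    t = t, df = df, p = 2 * pt(-abs(t), df),
    mean_a = ma, mean_b = mb, degenerate = FALSE
  )
}

#' Hierarchical mean ± s.e.m.
#'
#' The pooled summary convention used throughout: values are first averaged
#' within each group (oocyte), then the mean and standard error are taken
#' across group means. With one value per group this reduces to the flat
#' mean ± s.e.m.; with a single group the s.e.m. is undefined (`NA`).
#'
#' @param values Numeric vector.
#' @param group Optional grouping vector (same length); `NULL` treats every
#'   value as its own group.
#' @return A one-row tibble: `mean`, `sem`, `n_groups`.
#' @export
mean_sem <- function(values, group = NULL) {
  if (!length(values)) abort("`values` must be non-empty")
  if (is.null(group)) group <- seq_along(values)
  gm <- tapply(values, group, mean)
  n <- length(gm)
  tibble::tibble(
    mean = mean(gm),
    sem = if (n > 1) sd(gm) / sqrt(n) else NA_real_,
    n_groups = n
  )
}
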
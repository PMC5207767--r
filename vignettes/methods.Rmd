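---
title: "Models and methods behind the cymage pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the cymage pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`cymage` quantifies single-molecule TIRF movies of membrane proteins
carrying genetically encoded cyanine-dye amino acids. This vignette records
the models, parameter choices and numerical decisions behind each stage, in
enough detail that a maintainer can judge what the pipeline does and does
not guarantee.

## The synthetic movie generator

Real oocyte movies for this kind of experiment are not publicly deposited,
so the generator is a first-class part of the package: it defines the
conditions under which every downstream stage is validated.

**Spot placement.** Spots are a homogeneous Poisson process at the
condition's density. The presets carry the reported membrane densities:
encoded Cy3 0.14 spots/µm² and Cy5 0.08; mock Cy3 0.03 and Cy5 0.02. A
fraction `colocalized_fraction` of Cy5 spots is relocated to a Cy3 spot's
position plus the channel registration offset (default (1, 2) px, within the
1–2 px mapping error such two-camera fields show). The encoded preset uses
0.12: the observed ~14% colocalization in such experiments includes a few
percent of chance overlap, so the *true* pairing rate behind it is a little
lower; mock uses 0.

**Fluorophores per spot.** Encoded spots draw their fluorophore count from
(0.35, 0.30, 0.20, 0.10, 0.05) over 1–5 — a distribution visibly shifted to
2+ with occasional 4- and 5-step spots, as encoded-condition bleaching
shows; mock uses (0.85, 0.12, 0.03), dominated by single-step events. These
shapes are design choices (the study reports histograms, not a parametric
law); what the tests then verify is *recovery* of whatever distribution the
generator used.

**Bleaching.** Each fluorophore bleaches at an i.i.d. exponential time with
rate 0.03/s, converted to frame indices at 1 frame/s. At 100 frames this
leaves ~5% of fluorophores unbleached, so a realistic minority of traces is
rejected for incomplete photo-destruction — deliberately nonzero so the
rejection path is exercised. Bleach times are clamped to frame ≥ 1 so every
fluorophore is visible in the detection frame. Blinking and dark-state
recovery are not simulated by default.

**Image formation.** Each live fluorophore contributes a pixel-integrated
2-D Gaussian (products of `pnorm` differences, so mass is conserved exactly
up to truncation) of `unit_intensity` = 3000 AU at `psf_sigma` = 1.2 px;
background is a plane (500 AU offset, (0.5, 0.3) AU/px gradient); noise is
per-pixel Poisson scaled by the camera gain plus Gaussian read noise
(10 AU). The intensity scale was chosen once so that the conventional
grayscale detection thresholds (150–190 for Cy3, 130–150 for Cy5) sit
sensibly between the residual background and a single fluorophore's peak
pixel (~315 AU): a single dye is detectable, and the threshold genuinely
gates. Pixel size is a required physical input; presets use 0.2 µm/px, a
plausible 60× EMCCD scale, and that value is arbitrary in the sense that
nothing downstream assumes it beyond unit conversion.

**What the generator does not emulate:** wavelength-dependent evanescent
penetration (the higher Cy5 background of real rigs — per-channel offsets
are exposed instead), EM-register gain cascades, stage drift, and spatially
varying PSFs. Passing end-to-end tests therefore show the *algorithms*
recover known truth under this model, not that any specific biological
dataset would give identical numbers.

## Background subtraction

The background estimator is the exact grayscale morphological opening with
a ball (spherical cap) structuring element of radius 50 px: erosion
`min_s f(x+s) − b(s)` followed by the adjoint dilation, with
`b(s) = sqrt(r² − |s|²)` at 1 AU per px of height. This is the classical
"rolling ball" model — the background is the surface a ball of that radius
traces under the image; features too narrow for the ball (diffraction-limited
spots) are excluded from it. ImageJ's familiar implementation approximates
the ball with a paraboloid and optionally pre-smooths; our operator is the
exact one, tested against a brute-force erosion/dilation oracle, and is
anti-extensive and idempotent by construction (out-of-bounds offsets are
skipped, which preserves the adjunction).

One consequence matters quantitatively: on a noisy image the opening rides
the *lower envelope* of the noise, sitting ~2–3 noise standard deviations
below the true background level. Summed over a 7×7 AOI that bias is of the
same order as one fluorophore's intensity, which would wreck the
bleached-to-zero test. `subtract_stack()` therefore recenters the opening by
the median of `frame − opening` (spots are sparse, so the median residual
estimates exactly this envelope gap); the corrected frame then has median
~0. Subtraction itself is `max(frame − background, 0)`, and the background
is estimated on the first frame and reused across the stack by default (the
cellular background is static on the movie timescale; per-frame estimation
is available). The residual positive offset that zero-clipping leaves in
integrated traces (~0.4σ per pixel) is absorbed by the step counter's
baseline rule, below.

## Spot detection and number density

Detection follows the fixed-AOI convention: pixels at or above the
threshold form 8-connected components; components with area in
[`area_min` = 2, `area_max` = 80] px² become candidates at their
intensity-weighted centroid rounded to the nearest pixel; candidates closer
than `min_separation` = 4 px collapse to the brightest; a 7×7 window is
anchored at each survivor and windows that would leave the frame are
dropped. Connectivity, rounding and tie-breaks are fixed for determinism
(ordering by row then column). The area ceiling of 80 px² was sized so the
brightest legitimate spots (~20–25 px² at these settings) and close pairs
(40–60 px² when their disks touch) pass, while ruling out large debris.

Two refinements serve the number-density estimate, which would otherwise be
biased low by double-digit percentages at 0.14 spots/µm²:

* **Maxima splitting** (`split_merged = TRUE`): a component holding several
  regional intensity maxima at least `split_sep` = 3 px apart is split into
  one candidate per maximum, pixels assigned to the nearest kept maximum.
  3 px is the practical two-point resolution of a σ ≈ 1.2 px PSF — closer
  pairs do not produce separate maxima and cannot be told apart.
* **Overlap-corrected density**: for Poisson-placed spots, each unresolvable
  pair within the resolution distance `d` costs one count, so
  `E[N_obs] ≈ n − n²·πd²/(2A)`. `density_estimate()` inverts this quadratic
  (`n̂ = (1 − sqrt(1 − 4cN))/(2c)`, `c = πd²/2A`), removing the remaining
  few-percent bias. At mock densities the correction is negligible.

Density is counted from candidates *before* duplicate-merging and window
clipping (`count_spots()`): those two stages are constraints of trace
extraction, not of counting, and dropping border AOIs alone discards ~9% of
genuine spots on a 128 px field. Densities are reported per movie and pooled
hierarchically (per-oocyte means, then mean ± s.e.m. across oocytes).

## Trace extraction and step counting

A trace is the plain sum of the 7×7 window at each frame. The noise scale
σ̂ is estimated robustly as `1.4826 · median|Δv| / sqrt(2)` — successive
differences are insensitive to the handful of true steps.

The counter fits a piecewise-constant model by greedy change-point
insertion: at each round, the split maximizing the within-segment variance
reduction is proposed; it is accepted if the reduction exceeds the per-step
penalty `λ·σ̂²·log T` (λ = 3) *and* the implied step amplitude is at least
`min_step_snr` = 2 noise SDs. Each insertion is followed by local
refinement (each change point re-optimized within its flanking segments
until stable). When the best single insertion fails the gates, a two-step
lookahead still accepts a *pair* of change points if jointly they clear
twice the penalty and every resulting amplitude clears the SNR gate — this
covers short excursions no single step explains, and empirically makes the
greedy fit coincide with an exhaustive penalized search on short traces
(the suite checks 1,000 instances). With σ̂ = 0 (noise-free traces) the
fitter inserts steps until the residual is numerically zero, which makes it
exact on noiseless staircases.

Classification mirrors the manual convention: only traces whose fitted
levels strictly decrease and that bleach to completion are accepted. An
upward fitted step flags blinking or aggregation; a final level above
baseline flags incomplete photo-destruction. "Baseline" allows
`max(3·σ̂/sqrt(n_last), 0.5·min step amplitude)` — the second term absorbs
the clipping offset of real pipeline traces while still cleanly separating
a leftover fluorophore (one full step above baseline) from none. On
synthetic unclipped traces the rule reduces to the plain z-test.

Histograms pool absolute counts per movie (study designs use equal movie
numbers per condition, so absolute histograms are comparable); relative
frequencies go per movie → per-oocyte mean → pooled mean ± s.e.m., and
per-step-number condition comparisons use the equal-variance two-tailed
t-test on per-oocyte frequencies.

## Colocalization and the rotation null

Cy5 AOIs are mapped onto the Cy3 field by subtracting the registration
offset (supplied, or estimated by maximizing matches over integer shifts —
deterministic, ties to the smallest shift). A Cy5 spot is colocalized when
at least one Cy3 AOI center lies within Chebyshev distance 2 px: the square
metric matches the square windows, and 2 px covers the mapping error. There
is no exclusive matching and no intensity criterion on the partner.

The random-overlap null rotates the Cy5 coordinates 90° about the image
center ((r, c) → (c, H−1−r), restricted to the largest centered square for
non-square frames) and rescores. The rotation is an isometry, so it
preserves the pattern's density and internal geometry while destroying true
pairings; for two independent CSR channels, observed and null fractions are
statistically indistinguishable, and both match the closed form
`1 − exp(−λ(2r+1)²·px²)` for pixel-snapped coordinates. Both the
uncorrected and the null-subtracted fraction are reported (whether the
original analyses subtracted the null is not stated; we expose both, and the
recovery tests use `(obs − null)/(1 − null)`, the estimator implied by
`obs = f + (1−f)·null`).

## Closed-form quantifications

* Ligation efficiency `A_dye·ε_RNA/(A_RNA·ε_dye)·100%` with
  ε = 696,100 (suppressor tRNA at 260 nm), 150,000 (Cy3 at 550 nm),
  250,000 (Cy5 at 650 nm) M⁻¹cm⁻¹; LD550 has no published coefficient and
  requires a user-supplied value. Values over 100% are allowed but flagged.
* Percent-of-control luminescence, full precision internally, integer
  rounding only for display.
* Fold-over-background with the delta-method s.e.m. for a ratio of
  independent means (the error-propagation method is not stated in such
  reports; the delta method is the standard choice and is cross-checked
  against a bootstrap in the tests).
* Decay time to a fraction of peak: peak = maximum |I| at or after a
  configurable onset; the crossing of `fraction·|I_peak|` is linearly
  interpolated between samples, so an exponential with time constant τ
  returns τ·ln(10) to well within one sampling interval. For an
  instantaneous step the interpolated crossing lands inside the single
  interval containing the drop — "immediate" only up to the sampling
  interval, which is the operation's stated precision anyway.
* The two-sample equal-variance two-tailed t-test is implemented from the
  closed form (pooled variance, df = n₁+n₂−2) and verified against
  `stats::t.test(var.equal = TRUE)`; degenerate zero-variance inputs return
  t = 0, p = 1 for equal means and are flagged otherwise. Calibration is
  checked empirically (type-I error at α = 0.05 within [0.04, 0.06] over
  10,000 null simulations).

## Problem sizes and determinism

End-to-end validation runs at 128×128 px (655 µm² at 0.2 µm/px), 100 frames,
5 simulated oocytes per condition — enough for ~460 encoded Cy3 spots
pooled, which puts 2-Poisson-SE density recovery and total-variation ≤ 0.1
on the inferred fluorophore distribution within reach of an unbiased
pipeline while keeping a full run in tens of seconds. All stochastic stages
take explicit seeds; one master seed derives per-stage child seeds, and a
fixed seed reproduces rendered stacks bit-identically.

## Known limitations

* Two spots closer than ~3 px are fundamentally one detection; the density
  correction removes the aggregate bias but per-spot traces of such pairs
  mix their steps.
* Step counting assumes piecewise-constant intensity with roughly stationary
  noise; traces with strong photophysics (blinking, long dark states) are
  rejected rather than modelled.
* The never-bleached rejection combined with finite movie length slightly
  thins high-step-count spots (all *n* fluorophores must bleach within the
  movie); at the default rates this shifts the inferred distribution by a
  few hundredths of total variation.
* The rotation null assumes the spot pattern has no 90°-rotational
  structure; for fields with strong anisotropy a translation null would be
  preferable.
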
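# cymage

Single-molecule TIRF quantification of genetically encoded cyanine-dye
amino acids in membrane proteins.

When a fluorescent non-canonical amino acid (a Cy3- or Cy5-dye conjugate
delivered by a misacylated suppressor tRNA) is encoded into a plasma-membrane
channel expressed in *Xenopus* oocytes, TIRF microscopy of the membrane shows
sparse diffraction-limited spots. Three quantities demonstrate that the dye
really sits in the protein rather than floating free:

1. **Number density** of spots per µm² of membrane, higher in the encoded
   condition than in a mock control;
2. **Two-channel colocalization** — the fraction of Cy5 spots with a Cy3
   partner, compared against a random-overlap null built by rotating one
   channel 90° about the image center;
3. **Photobleaching step counts** — a spot carrying *n* fluorophores bleaches
   in *n* discrete downward intensity steps, so the step histogram bounds the
   labelled-subunit stoichiometry (the encoded condition shifts towards 2+
   steps; mock is single-step dominated).

`cymage` implements this pipeline end to end, for users analysing such
movies and for anyone who needs a tested, scriptable version of the classic
CoSMoS-style analysis: rolling-ball background subtraction (grayscale
opening with a ball structuring element, radius 50 px), first-frame spot
detection into fixed 7×7 areas of interest, integrated-intensity trace
extraction, automated step counting by penalized change-point fitting, and
per-movie → per-oocyte → pooled aggregation with the study's statistics
(equal-variance two-tailed t-tests, hierarchical mean ± s.e.m.). A synthetic
two-channel movie generator with known ground truth (Poisson spot placement,
pixel-integrated Gaussian PSF, exponential bleaching, EMCCD-style noise)
makes every stage testable without any raw data.

The step counter replaces the study's manual trace classification: it fits a
piecewise-constant model by greedy insertion of the change point with the
largest variance reduction (with local refinement and a two-step lookahead),
stopping at a per-step penalty λσ²·log T and a minimum step-to-noise ratio;
traces with an upward step (blinking/aggregation) or that never bleach to
baseline are rejected, mirroring the "complete photo-destruction" rule.

The package also covers the surrounding closed-form quantifications: tRNA
ligation efficiency from absorbances
(`eff% = A_dye·ε_RNA / (A_RNA·ε_dye) · 100`), percent-of-control
luminescence, fold-over-background currents with delta-method errors, and
the time for a peak current to decay to 10%.

## Worked example

```r
library(cymage)

spec  <- condition_spec("encoded")   # densities 0.14 / 0.08 spots/µm², ...
cam   <- camera_model()              # PSF σ = 1.2 px, EMCCD-style noise
field <- simulate_spot_field(spec, dim = c(128, 128), pixel_size = 0.2,
                             n_frames = 100, seed = 11)
stack <- render_movie(field, cam, "Cy3", seed = 12)
corr  <- subtract_stack(stack, radius = 50)
res   <- analyze_stack(corr)

res$density
#> [1] 0.1355054
table(res$fits$n_steps[res$fits$accepted])
#>
#>  1  2  3  4  5  6
#> 19 17 10  6  1  2
```

The recovered density (`0.136` spots/µm² here) estimates the generator's
0.14 from one 655 µm² movie; the accepted-trace step table is the raw
material of the bleaching histogram (`aggregate_step_histogram()`,
`compare_step_distributions()`). `autoplot()` methods draw traces with
fitted steps and pooled step histograms; `tidy()`/`glance()` turn fits and
histograms into tibbles.

Colocalization on the same field:

```r
res5 <- analyze_stack(subtract_stack(render_movie(field, cam, "Cy5", seed = 13)))
coloc_analysis(res$aois, res5$aois, dim = c(128, 128),
               offset = spec$registration_offset, tolerance = 2)
```

which reports the observed fraction, the 90°-rotation null, and their
difference.

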
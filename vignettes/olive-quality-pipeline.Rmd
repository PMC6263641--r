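---
title: "Methods: from olive tray images to oil quality predictions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from olive tray images to oil quality predictions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`olivescan` estimates the chemical quality of the virgin olive oil that a
batch of fruit will yield, from a single RGB photograph of the batch on a
white tray. This vignette documents the model, the choices behind every
tunable, and what the synthetic test bed does and does not demonstrate.

## The measurement model

The pipeline assumes the two drivers of oil quality that a trained yard
inspector scores visually are expressed in the fruit's appearance:

* **ripeness**, visible as skin colour (green → purple → black), carried by
  the colour-channel means;
* **health**, visible as skin damage, carried by the texture heterogeneity
  of the fruit surface.

Both are low-dimensional latent properties of a batch, which is why a
latent-variable regression (PLS) is the natural model: ten chemistry
parameters are regressed one at a time on 23 image features that are
themselves noisy views of a few underlying factors.

## Imaging stage

* **Grayscale**: Rec. 601 luma (0.299, 0.587, 0.114), rounded to 8-bit.
  This is the conventional broadcast weighting and the only place the
  conversion weights appear.
* **Binarisation polarity**: fruit pixels are those *below* the threshold
  — dark fruit on a near-white tray.
* **Threshold**: `"auto"` (default) maximises Otsu's between-class
  variance on the 256-bin histogram. For a well-separated bimodal
  histogram the criterion is constant anywhere between the two modes; we
  take the *midpoint* of that plateau, which keeps the cut far from both
  modes (the first-argmax convention would sit directly above the fruit
  mode and mislabel antialiased fruit rims). A fixed threshold can be
  pinned via `feature_settings(threshold = ...)` for strict
  reproducibility across acquisition sessions.
* **No morphological cleanup** is applied by default; with a white tray
  and the plateau-midpoint threshold, segmentation of the synthetic scenes
  recovers ≥ 99% of true fruit pixels (tested), so opening/filling would
  only add parameters.

## Feature stage

The 23 features are 9 colour means plus 14 Haralick descriptors; this
9 + 14 decomposition counts the two information measures of correlation
separately.

**Colour means.** The default `mean_mode = "all_pixels"` divides each
masked-channel sum by the full pixel count `N × M`, so the zeroed
background dilutes the mean by the fruit coverage. This is deliberate: the
whole-image mean is the conventional whole-tray definition, and coverage
itself carries information (bigger/more fruit). The coverage-invariant
alternative `"fruit_only"` averages over mask pixels only and is the right
choice when tray loading varies; both are exposed because the correct
definition depends on the acquisition protocol. Hue is averaged
arithmetically like every other channel by default; hue is an angle, so a
circular mean (`hue_circular = TRUE`, fruit-only) is offered, but olive
skin hues live on a short green–red arc where the seam at hue = 1 is not
crossed, so the plain mean is adequate and simpler to interpret.

**Colour spaces.** HSV via the standard hexcone model (all channels scaled
to [0, 1]); CIELAB under sRGB primaries and the D65 white point — the
default for consumer colour cameras. Both conversions are delegated to
`grDevices`.

**GLCM.** Texture is computed on the grayscale of the masked image, with
pair counting restricted to pairs whose *both* pixels are fruit: including
the zeroed background would otherwise dominate every statistic with
background–background and edge pairs. Defaults: 64 quantisation levels
over the fixed range [0, 255] (fixed, so matrices are comparable across
images), distance 1, the four standard directions accumulated, symmetric.
All are configurable; 64 levels keeps the 64×64 matrix well populated at
quarter-resolution scenes while retaining enough dynamic range for the
blotch contrast.

**Haralick conventions** (all documented in `haralick_features()`):
natural logarithms; zero-probability cells contribute zero (no epsilon
inside logs); the "variance" feature is the variance of the row marginal;
sum variance is taken about the *sum average* (the classical text's
self-reference to sum entropy at that point is a known erratum);
the maximal correlation coefficient is the square root of the
second-largest eigenvalue of the Q matrix restricted to the marginal
support, clipped to [0, 1]. Degenerate matrices (a marginal concentrated
on one level) return correlation 0, IMC1 0 and MCC 0 with an
`mcc_degenerate` attribute — flags, not exceptions, so a flat fruit region
cannot crash a batch run. Every descriptor is verified against an
independent brute-force double-loop oracle to 1e−10 on random matrices.

## Regression stage

**PLS1 by NIPALS**, one response at a time. Preprocessing defaults to
autoscaling X (centre, unit variance) and centring y — the standard
chemometric practice when features mix units as different as hue ([0, 1])
and polyphenol-scale intensities; centre-only is available. Numerical
guards: weight-change tolerance 1e−10 with a 500-iteration cap (PLS1
converges in one pass; the guard is kept for safety), and explicit rank
handling — when the deflated X or its covariance with y vanishes before
the requested number of components, `fit_pls()` errors by default or
truncates on request (`on_rank_deficit = "truncate"`), which is what the
validation loop uses so a low-rank calibration half cannot abort a sweep.
At full feasible rank the coefficients coincide with ordinary least
squares (tested to 1e−6), and scores are mutually orthogonal with
`T P' + E` reconstructing the processed X exactly.

**Validation protocol.** Each candidate `lv` from 1 to 23 (capped by the
feature count, the effective rank of the scaled X, and the
calibration-half size) is assessed by repeated random 50/50 holdout —
1000 repetitions by default. The same split sequence is reused across the
whole sweep (common random numbers), so candidates are compared on
identical partitions and the sweep curve is not jittered by split noise.
Splits are simple random draws, not stratified. The selected model
minimises mean validation RMSE, with ties broken toward fewer latent
variables (parsimony). Reported values are means over repetitions;
dispersions are reported alongside because a single 50/50 split of ~74
batches is noisy. RPD is computed per repetition as the validation-half
standard deviation (divisor n − 1) over that repetition's RMSEv, then
averaged — so within each repetition `RPD × RMSEv` equals the
validation-half sd exactly (an identity the tests check to 1e−9). Both
R and R² are derivable from the report; the tables print R².

## The synthetic test bed

**Scenes.** A batch is rendered as 25–40 filled ellipses (semi-major axis
10–18 px) on a 512 × 272 tray at background grey 235 — one quarter of the
2048 × 1088 acquisition frame, for speed; the full frame is one
configuration away. Skin colour interpolates a green → purple → black
palette at a per-fruit ripeness jittered ±0.2 around the batch latent;
fruits get mild radial shading, and a `spoilage` fraction of them receive
2–5 dark/brown disk blotches painted on the skin only. Per-pixel uniform
noise (±4 grey levels) is added everywhere; the green palette anchor
dominates red/blue by far more than twice the noise bound, so a fully
green batch stays strictly green-dominant pixelwise. Blotch randomness is
drawn after all geometry and pixel noise, so two scenes sharing a seed
differ only in their blotches — this makes paired spoilage comparisons
exact rather than statistical.

**Categories.** The four visual categories are deterministic functions of
the latents: Cat-1 below 50% ripeness; ripe batches (50–85%) split into
healthy Cat-2 and spoiled Cat-3 at 30% spoilage; Cat-4 at ≥ 85% ripeness.

**Chemistry link.** Each parameter responds as
`intercept + b_r·r + b_s·s + b_q·r²` plus Gaussian noise. The quadratic
term is essential, not cosmetic: ethyl esters and peroxides are strongly
convex in ripeness (they barely move between green and healthy-ripe
batches, then surge in spoiled/overripe ones), and a purely linear link
cannot reproduce the published category-level means while keeping the
implied healthy-ripe mean inside that category's observed min–max range.
The four coefficients are therefore solved *exactly* through the four
category-centroid calibration means (the 4 × 4 design (1, r, s, r²) at the
centroids is invertible because ripeness takes three distinct values and
spoilage separates the tied pair). The same solve automatically yields the
known polyphenol behaviour — concave in ripeness (fitted b_q = −1551,
vertex at r ≈ 0.64, near the healthy-ripe centroid) with a negative
spoilage coefficient, peaking at Cat-2 — and the monotone category
orderings of acidity (rising) and pigments (falling). Noise standard
deviations default to roughly a third of each parameter's
between-category spread, comparable to the within-week dispersion of real
campaign data; `default_chem_link(noise_sd = ...)` overrides them. An
optional eleventh parameter, `control`, is pure noise with no latent link
and serves as the negative control in end-to-end tests.

**What passing tests show — and what they don't.** The generator gives
the analysis exactly the structure it assumes: ellipses on a clean white
tray, colour monotone in ripeness, texture monotone in spoilage, chemistry
low-dimensional in the same two latents. Success on it demonstrates the
pipeline's internal correctness (segmentation, feature definitions,
regression and validation machinery) and end-to-end signal recovery. It
does **not** demonstrate field performance: real trays have leaves, stems,
dirt, specular highlights, touching-fruit occlusion, variety-dependent
palettes and chemistry that is neither exactly quadratic nor
two-dimensional in its drivers. Real-data validation is irreducible.

## Recovery benchmarks and their design

`generate_feature_table()` builds feature matrices from `lv_true` latent
factors (`X = T L'`) with a response in the same factors plus noise, and
returns the minimum-norm true coefficient vector. Recovery checks
(selected `lv`, coefficient cosine ≥ 0.95 at 10% noise, validation RMSE
within 10% of the generating noise sd at n = 500) are run with
**centre-only** preprocessing: under autoscaling the back-transformed
coefficient vector is divided componentwise by the per-column sd, which
takes it out of the generating factor span and makes cosine-to-truth
meaningless as a recovery metric (it sits near 0.6 even for a noiseless
fit, despite perfect predictions). With centring only, the estimate stays
in the span and the cosine reaches 1.000. Autoscaling remains the default
for the real pipeline, where features have incommensurable units — the
two choices answer different questions.

## Problem sizes

Sizes used by the shipped tests and the acceptance script, chosen to keep
a full run in the minutes range while leaving all statistical conclusions
stable: most image tests use 160 × 120 scenes with 4–6 fruits; the
simulated campaign uses the study-scale 74 batches at quarter resolution
with 200 holdout repetitions; recovery benchmarks use n = 500, p = 23 with
100 repetitions; determinism checks use 16 batches and 50 repetitions.
Defaults in the package itself stay at the protocol values (1000
repetitions, sweep to 23).

## Known limitations

* Whole-batch features only: no per-fruit instance segmentation, counting
  or sizing.
* The all-pixel colour means conflate coverage with colour by design; use
  `fruit_only` when tray loading is not controlled.
* The arithmetic hue mean is seam-blind for hues near red; the circular
  option exists but is not the default.
* Simple random (unstratified) holdout splits; with ~74 batches a rare
  split can under-represent a category.
* The Lab conversion assumes sRGB/D65; a colour-managed camera pipeline
  should convert with its own profile before feature extraction.
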
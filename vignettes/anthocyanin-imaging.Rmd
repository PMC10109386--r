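---
title: "Methods: image-based anthocyanin phenotyping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: image-based anthocyanin phenotyping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anthoimg)
```

## The measurement model

Anthocyanins absorb green light (~500–550 nm) effectively and red light
hardly at all; chlorophyll absorbs in both green and red. A leaf's green
reflectance therefore falls as anthocyanin accumulates, while its red
reflectance reflects chlorophyll. Indices built from green and red
reflectance can separate the two pigments; indices that replace red with
NIR cannot, because NIR reflectance is governed by leaf structure, not
pigments.

The package treats an 8-bit pixel intensity `I` of a gray-card-calibrated
band image as a reflectance proxy, with `R = I / 255` in [0, 1]. Six
per-pixel indices are provided (NDAI, NARI, ARI, mACI, mARI, RGI; see the
README table). Three are pure same-scale ratios (NDAI, NARI, RGI) and may
be computed on intensities directly; ARI, mACI and mARI take reciprocals or
cross-band ratios of reflectance and are always computed on the `/255`
scale. `compute_index()` performs the conversion automatically and refuses
stacks whose bands carry different digital gains, since a gain mismatch
silently distorts every ratio index.

### Calibration

A middle-gray card reflects 50% at all wavebands, so a correctly exposed
image of it should read intensity 127 of 255. The calibration is a single
global gain per band, `127 / measured_gray`, applied digitally
(`apply_gain()`); the target is the printed integer 127 rather than 127.5,
accepting a bias below 0.4%. Sensor response is assumed linear — an
assumption any single-point gray correction makes. Flat-field (per-pixel)
and gamma corrections are out of scope. Rounding after the gain is
half-away-from-zero (base R's `round()` is round-half-even, which would
treat the 0.5 boundaries asymmetrically across the intensity range), and
clipped pixel counts are always reported.

### Segmentation

Band stacks are thresholded on one band — by default NIR, where vegetation
is bright and most backgrounds dark — either at a fixed cutoff or by Otsu's
criterion (the 256-bin threshold maximizing between-class variance; a
constant image has no separable classes and is an error). Small connected
components are then removed (despeckling); components are 8-connected so
that diagonally touching leaf parts are not split. RGB images are
thresholded on the red:blue ratio — leaves absorb blue strongly, so plants
sit well above 1 while a gray floor sits at 1 — with the blue denominator
floored at 1, followed by erosion and dilation with a square kernel.

No universal threshold or kernel settings exist for such scenes, so the
defaults (Otsu; ratio 1.2; 3×3 kernel, one erosion, one dilation; minimum
component 16 px) are starting points, all exposed in
`segmentation_params()` and the CLI config. Opening (equal erosion and
dilation counts) and despeckling are idempotent, which the tests assert.

### Summaries and evaluation

`index_summary()` reports mean, standard deviation, CV, range and a
histogram over valid plant pixels only; pixels where a formula is
undefined (zero denominators) are counted separately, never given sentinel
values. The standard deviation is the population (n-denominator) form: the
pixels are the full population of the imaged object, not a sample from it.
Histograms default to 50 bins over the theoretical range for bounded
indices (NDAI/NARI: [−1, 1]) and the data range otherwise.

Index evaluation regresses **index on concentration** (the direction such
calibrations are plotted in), by ordinary least squares via `stats::lm`,
linear and quadratic, selected by AIC. The reported statistics are
R² = 1 − RSS/TSS, RMSE = √(RSS/n) (n denominator, index units), the
least-squares AIC `n·log(RSS/n) + 2k` with k counting coefficients plus
the error variance, and the overall-F p-value. Model-selection ties
(ΔAIC < 1e-9) favor the linear model, as does a linear fit that is already
exact to machine precision — comparing AICs of two near-zero residual sums
would be numerical noise. With fewer than four points the quadratic is
infeasible and the linear fit is returned with a warning flag.
`predict_concentration()` inverts the selected curve numerically,
restricted to the calibration range; a quadratic that turns around inside
the range, or an index value outside the fitted span, is refused rather
than extrapolated.

## The synthetic-scene generator

Because the pipeline's accuracy claims must be testable without real
imagery, the generator renders leaf discs (grid layout) or rosettes
(overlapping leaves around the center) with known ground truth. The
forward model is Beer–Lambert in style:

```
R_green = Rg0 · exp(−a·c − b_g·chl)
R_red   = Rr0 · exp(−b_r·chl)
R_nir   = Rn0
```

with `c` the anthocyanin concentration (µg g⁻¹ FW) and `chl` a
chlorophyll level in arbitrary units. Only the *direction* of these
dependencies is established leaf optics; the exponential form is the
simplest positive, monotone choice. Defaults
(`Rg0 = 0.34, Rr0 = 0.28, Rn0 = 0.55, a = 4.5e-4, b_g = 0.10,
b_r = 0.15`) were set once so that object-mean NDAI spans roughly −0.1 to
0.25 over the default concentration range 108–1673 µg g⁻¹ FW — the span
reported for cold-stressed red lettuce — with chlorophyll varying modestly
(0.8–1.2). NIR is deliberately pigment-independent (leaf structure), which
lets the tests demonstrate that chlorophyll variation disturbs mACI far
more than NDAI. Gaussian pixel noise (reflectance units, default 0) is
added before clipping to [0, 1] and 8-bit quantization
(half-away-from-zero; a noiseless reflectance therefore survives
quantization within 1/510).

The RGB renderer builds a coarse per-pixel reflectance curve by linear
interpolation through four anchors — 450, 516, 664 and 861 nm — and
integrates it against each channel's effective response (Gaussian
sensitivity × warm-white LED illuminant, renormalized). Channel peaks
default to 450/521/596 nm with half-maximum spans of roughly 477–595 nm
(green) and 580–700 nm (red), emulating the broad, overlapping responses
of a consumer camera module under warm-white light. The 450 nm plant
anchor (`blue_anchor`, default 0.06) is a deliberate addition to the
three-band forward model: leaves absorb blue strongly, and without a low
blue reflectance the red:blue ratio — the very contrast RGB segmentation
relies on — would not exist in the synthetic scenes. The background is
spectrally flat, so its ratio is exactly 1. Because interpolation is
linear in the anchor values, each channel reduces to a fixed 3×4 weight
matrix, and narrowing the channel sensitivities onto the band peaks makes
RGB-derived NDAI converge to the multispectral value — a limit the tests
exercise.

What the generator does **not** emulate: specular highlights and shadows,
out-of-focus blur, vein structure and within-leaf pigment gradients,
illumination non-uniformity, and radiative-transfer realism
(PROSPECT-class models). Passing tests therefore demonstrate the
*software's* correctness and the indices' behavior under the stated
forward model, not field performance on real canopies.

## Determinism and problem sizes

Every render derives all randomness (pigment draws, then per-band noise)
from the scene seed, restoring the caller's RNG state afterwards; the
multispectral and RGB renderers share the pigment draw order, so one spec
rendered both ways has identical ground truth. Evaluation sets derive
per-sample seeds from one master seed and are byte-reproducible.

The shipped tests and the acceptance script use 64×64 px single-disc
scenes (50 discs for recovery checks, 30 for cross-system checks, 20 for
segmentation recovery), an exhaustive 256×256 sweep for the NDAI bounds
and 10⁵ random pairs for the NARI/NDAI identity — sizes at which every
property is already decisive while the whole suite runs in seconds.

## Known limitations

* Top-view imaging sees only the top leaf layer; the indices say nothing
  about obscured lower leaves or abaxial pigment.
* Index values depend on the illumination spectrum; comparisons are only
  valid across images taken under the same light and calibration.
* The calibration is a single global gain: spatial illumination gradients
  are not corrected.
* Segmentation defaults are scene-dependent and will need adjustment for
  backgrounds that are not spectrally flat or NIR-dark.
* The concentration inversion is only as good as the fitted calibration
  and refuses to extrapolate beyond it.
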
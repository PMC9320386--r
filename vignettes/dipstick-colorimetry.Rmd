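---
title: "Semi-quantitative dipstick colorimetry: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semi-quantitative dipstick colorimetry: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dipstickr)
```

## The measurement model

A urine dipstick carries reagent pads whose color shifts with the
concentration of an analyte. When a pad is photographed with a
smartphone, the pad's mean color is an 8-bit RGB triplet, and for each
analyte one color channel responds most linearly to concentration. The
package models that response as

$$Y = a X + b \qquad \text{or} \qquad Y = a \log_{10} X + b,$$

where $Y$ is the optimized channel's mean value (0–255), $X$ the analyte
concentration, and $(a, b)$ are fitted by ordinary least squares.
Linearity is scored by $r^2 = 1 - SS_{res}/SS_{tot}$, and the channel
with the highest $r^2$ among R, G, B (optionally H, S, V) is the
*optimized channel*. Reading a strip inverts the fitted formula:
$\hat X = (Y - b)/a$, or $10^{(Y-b)/a}$ on the log scale, and maps
$\hat X$ to an ordered semi-quantitative category (negative / trace /
+ / ++).

The built-in panel ships seven analytes — pH, glucose, ketones,
hemoglobin, bilirubin, protein (albumin) and nitrites — each with its
optimized channel, fitted coefficients, $r^2$, and a *linearity range*:
the concentration interval over which color processing is reliable.
Inverse predictions outside that range are clamped to it and flagged
(`clamped = TRUE`) rather than rejected, so the caveat reaches the
caller without aborting a strip read. The clamp comparison uses a
relative epsilon of $10^{-9}$ so that responses generated exactly at a
range boundary do not flip the flag through floating-point rounding.

Two interpretation choices are worth stating. First, "log" calibration
is taken as base-10: the log-scaled analytes' ranges span whole decades
(5–100, 10–1000, 1–100), and decade structure is the natural readout
grid for dilution series. Second, pH enters the regression as the pH
value itself with `scale = "linear"`, since pH is already a logarithmic
quantity. For bilirubin, published channel screens disagree on whether R
or G is most linear; the built-in panel keeps the G-channel assignment
of the published calibration table and exposes `screen_linearity()` so
users can re-derive the choice on their own series.

## Regions of interest and color extraction

Pad localization is configuration-driven: the panel JSON records one
fractional, half-open rectangle per pad, `[x0, x1) x [y0, y1)` in units
of image width and height, so one configuration serves any resolution
(pixel windows come from `floor(frac * dim)` rounding). Each ROI is
shrunk by a fraction of its own extent on every edge — default 0.2 — to
avoid pad borders and shadows, and the remaining pixels are averaged per
channel (median available for robustness to specular highlights).
Automatic strip detection, perspective correction and white-balance
estimation are out of scope; capture conditions (illuminance, distance,
device) travel only as free-form metadata.

RGB-to-HSV conversion follows the standard hexcone model via
`grDevices::rgb2hsv`, with hue in degrees and the achromatic hue defined
as 0° so every channel is a total function usable as a regression
response. HSV channels enter regressions on their native scales (degrees
and unit fractions).

## Tunable parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `shrink` | 0.2 | fraction/edge | trims pad borders before averaging |
| `scale` | per analyte | — | linear vs log10 concentration axis |
| `channel_weight` | 2 | — | optimized-channel weight in the exemplar distance |
| `channel_sd` | 2 | 0–255 units | synthetic sensor noise sd |
| `gain` | 1 | — | global illumination gain in simulation |
| `conf_mult` | 1.96 | — | Bland–Altman limit multiplier (normal 95%) |
| `recommended_n` | 1000 | exemplars | maturity advisory for the store |

Default category schemes place the first bin edge at the analyte's
printed normal-range cutoff (glucose 20, ketones 5, bilirubin 0.2,
protein 2, in their concentration units) and the remaining edges at the
linearity-range endpoints; hemoglobin and nitrites have no printed
cutoff and use linearity endpoints only, and pH is graded
acidic/normal/alkaline on its 4.8–7.4 normal range. Bins are half-open
`[low, high)` so edge behavior is deterministic. All schemes are
plumbing, overridable per panel configuration.

## Agreement and the learning store

Agreement with a reference urine analyzer is summarized in Bland–Altman
form on numeric concentration estimates: differences are `test -
reference` (positive bias = the app over-reads), with limits of
agreement at bias ± 1.96 sd (sample sd, n−1). Label-level concordance is
the learning store's job, not Bland–Altman's.

The store treats analyzer readings as absolute labels and keeps every
labeled pad color as an exemplar. A new measurement snaps to the label
of the nearest exemplar in RGB, with the analyte's optimized channel
weighted ×2 — that channel carries the calibrated signal, the others
mostly context. Ties break toward the earliest-inserted exemplar, and
insertion order survives JSON persistence, so predictions are
deterministic. Online learning (`update()`) first predicts, then scores,
then appends the observation. An observation whose reference label has
never been seen for that analyte is a *per-class cold start*: it is
logged but not scored, because no exemplar of that class existed to
predict it — the same reasoning as not scoring the very first
observation, applied per class. Accuracy here means reproducibility:
the fraction of scored predictions that reproduce the analyzer's label
over repeated tests, computed through the one-vs-rest confusion matrix
(TP/FP/TN/FN bookkeeping). The store surfaces, without enforcing, an
advisory exemplar count of 1000 per analyte before accuracy figures are
considered stable.

## What the synthetic generator emulates — and what it does not

`simulate_pad_color()` is the forward model: the optimized channel takes
`gain x (calibration formula)` plus Gaussian sensor noise (default sd 2
on the 0–255 scale, a realistic magnitude for an 8-bit consumer sensor);
a single multiplicative gain stands in for illumination change. The two
channels the calibration table does not describe follow fixed,
documented quadratic ramps (`base + amp * t^2` with `t` the position
along the fit scale; constants in `R/synth.R`): visibly responsive, yet
strictly less linear than the optimized channel, so channel selection
remains identifiable from synthetic series. All channels clip to
[0, 255] and clipping events are counted on the result.

`dilution_series()` mirrors the calibration protocol (standard levels
spanning the linearity range, default 5, replicates per level);
`render_strip()` lays one square pad per analyte with per-pixel noise
and returns the exact ROIs, making the render→read round trip exact at
zero noise; `paired_device_dataset()` emulates the device-vs-app
comparison. Its default draws concentrations uniformly among the
category *bin-center* levels — repeated tests of standard solutions,
which is how reference comparisons are actually run — with
`sampling = "uniform"` available for continuous draws (log-uniform on
log-scaled curves). Device labels flip to an adjacent category with a
configurable probability, emulating analyzer reads at bin boundaries.

The generator does not model reflectance physics, camera response
curves, color casts, spatial illumination gradients, pad texture, or
reagent kinetics. Tests passing on synthetic data therefore demonstrate
the correctness of the calibration/inversion/learning machinery under
the stated noise model, not field performance on real photographs.

## Numerical choices and degenerate inputs

* OLS via `stats::lm`; $r^2$ computed explicitly so the zero-variance
  case is total: flat responses with zero residuals give $r^2 = 1$,
  anything else 0. Degenerate x (all identical) is an error.
* Channel-selection ties break by the fixed order R, G, B, H, S, V.
* Categorization at a bin edge goes to the upper bin (half-open bins).
* A failed pad (e.g. an ROI that holds no pixel after shrink at a given
  resolution) flags its own row in `read_strip()` and leaves the other
  pads untouched.
* Every stochastic generator accepts a seed through `noise_model()` and
  reproduces byte-identical output.

Test and example problem sizes (5-point series, 1000-draw round-trip
checks, 50-replicate noise studies) were chosen as the smallest sizes at
which the checked properties are empirically stable.

## Limitations

The calibration constants were established on artificial-urine dilution
series under controlled capture conditions; real urine matrices,
uncontrolled lighting and other camera models will shift both slopes and
noise levels, and panels should be refit (`calibrate` subcommand) for
any new hardware. The learning store is instance-based and per-analyte;
it does not share exemplars across users or model drift over time.
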
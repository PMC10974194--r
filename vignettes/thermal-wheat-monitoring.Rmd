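---
title: "Thermography-based wheat monitoring: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thermography-based wheat monitoring: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermowheat)
```

## The measurement problem

Passive long-wave infrared imaging of a wheat plot yields a raster of
surface temperatures in which two populations of pixels coexist: the crop
canopy, cooled below ambient by transpiration, and the bare soil between
and behind the rows, which runs several degrees warmer under daytime
radiation. Everything this package computes rests on separating those two
populations frame by frame and summarising their contrast.

Two per-frame indices are derived from the separation:

* **Wheat Stress Index**, `WSI = (T_S - T_W) / T_S`, where `T_W` and `T_S`
  are the mean temperatures of the wheat and soil pixel classes of the
  frame. Normalising by the within-frame soil temperature (rather than air
  temperature or wet/dry references) makes the index self-contained: no
  auxiliary instrument is needed, and the soil term absorbs microclimatic
  differences between plots. In the regime `T_S > T_W > 0` the index lies
  in (0, 1); a *lower* WSI means a *warmer* canopy relative to its soil,
  i.e. less transpiration and **more** stress. The ratio is taken on
  Celsius values and is deliberately not unit-invariant — the published
  summary values only reproduce in °C, so the package treats °C as part of
  the index definition.
* **Wheat Cover Index**, `WCI = P_W / (P_W + P_S)`, the fraction of
  classified pixels labelled wheat — a thermal proxy for fractional ground
  cover. It is only meaningful while the canopy is still open; the
  aggregation layer therefore computes it exclusively from stem-elongation
  frames, as an enforced rule rather than advice.

Per-variety summaries are unweighted means: each variety × stage cell
averages all frame-level WSI values (pooled over sessions and replicates),
`WSI_m` is the row mean over the four stages, `PP-WSI_m` the column mean
over the nine varieties. The package computes one WSI per frame and then
averages frames, rather than pooling all pixels first; the per-frame route
matches how the images are acquired and makes dispersion estimable. On a
complete table the grand means of rows and columns coincide, which the
tests assert.

## Segmentation: threshold from the temperature histogram

Pixels are classified against a single temperature threshold `T_TH`:

1. **Histogram.** Uniform bins over the valid-pixel range, default width
   0.1 °C. The camera class emulated here has a noise-equivalent
   temperature difference of roughly 60 mK, so finer bins would resolve
   sensor noise, and much coarser bins blur the valley between modes.
2. **Mode detection.** The counts are smoothed with a 5-bin moving average
   (shrinking windows at the edges, so a boundary mode survives). Local
   maxima are kept if their topographic prominence reaches 5 % of the
   tallest smoothed bin, and peaks closer than 1.0 °C are merged in favour
   of the more prominent one. All three parameters are exposed; the
   defaults suppress noise ripples while keeping wheat/soil modes that sit
   a few degrees apart.
3. **Threshold.** With exactly two modes, `T_TH` is their arithmetic mean.
   With more than two, the two most prominent are used. With fewer than
   two — a continuous, unimodal distribution — the fallback maximises the
   between-class variance over every bin edge (Otsu's criterion). The
   original field procedure resolved continuous cases by visual comparison
   with an RGB photograph; that step is not automatable, and Otsu is this
   package's formalisation of "maximise the separation of the two
   temperature classes". The choice is recorded per frame in the `method`
   field.
4. **Classification.** Pixels at or below `T_TH` are wheat, above it soil.
   The defining inequalities are strict on both sides and leave equality
   unassigned; the package assigns ties to wheat. Any fixed rule preserves
   count conservation (`P_W + P_S` = valid pixels), and at 0.1 °C bin
   resolution the tie mass is negligible; the rule is documented and
   tested rather than important.

Thresholds are selected per frame, not per plot: each frame's histogram
stands alone, which tolerates session-to-session temperature drift.

Two numerical edge cases are defined errors rather than silent results: a
frame with no valid pixels cannot be histogrammed, and a single-bin
(constant) histogram has no defined threshold. A frame whose pixels all
fall on one side of the threshold yields an empty class; the WSI for such
a frame is recorded as `NA` with a warning, never computed from a
single-class mean.

The thresholding carries an intrinsic error from the overlap of the two
temperature distributions: vegetation pixels warmer than `T_TH` count as
soil and vice versa. As in the original analysis, no correction is
applied; for class separations of several within-class standard
deviations the two error sets nearly cancel in `WCI` and bias `WSI` by
well under 0.01, which the recovery tests quantify.

## The synthetic field generator

The study's raw infrared sequences are not public, so the package ships a
seeded generator that emulates the acquisition design: two species × nine
varieties × four phenological stages × `sessions_per_stage` measurement
sessions, with `frames_per_session` frames per cell. Within a frame:

* The wheat mask is laid out as **vertical crop-row bands** whose widths
  are drawn from a 4–12 pixel pool, with the soil gaps jittered around
  them; the total wheat-column count equals the requested cover fraction
  exactly at one-column granularity. Banding (rather than i.i.d. pixel
  labels) gives masks that look like drilled rows and histograms that are
  genuinely bimodal.
* Pixel temperatures are Gaussian within class. The generator is
  parameterised by the soil mean and a **target WSI**; the wheat mean is
  derived as `soil_mean × (1 − target_wsi)`, never set freely, so the
  quantity the pipeline must recover is the quantity the generator was
  told.
* Each species × stage × session draws one additive temperature offset,
  Normal(0, 0.5 °C), applied to both class means. This emulates
  morning/afternoon sessions while preserving the target WSI in
  expectation (the denominator shifts slightly; over the default four
  sessions the induced cell-level error is a few thousandths).

Default conditions mirror the emulated protocol: four sessions per stage
(two per day on two consecutive days) and 10 frames per session at the
native 320 × 240 detector size. The acquisition protocol is described
inconsistently in the source material (30 images per session in one place,
20 in another); both counts are reachable through `frames_per_session` and
neither is asserted as canonical. Stress targets come from the published
per-stage WSI table and stem-elongation cover fractions from the published
WCI table; post-elongation cover defaults to 0.85 (closed canopy). Soil
means per stage default to 18, 26, 30 and 32 °C from stem elongation to
full ripening — the package's own choice of plausible Mediterranean
field-season values; no measured soil temperatures are available, and the
published example threshold of 16.2 °C anchors the April scale. Gaussian
class noise (0.5 °C) is likewise an assumption, not a measured property.

What the generator does **not** emulate: energy-balance canopy physics,
wind and shadow structure, diurnal radiation curves, plot geometry and
edge effects, mixed (sub-pixel) boundary pixels, or spatially correlated
sensor noise. Passing recovery tests therefore show that the pipeline
inverts its own generative model at realistic noise levels — a necessary
check with exact ground truth — not that it handles every pathology of
real field imagery.

## Correlation analysis

Per-variety index summaries (`WSI_m`, `WCI_m`) are related to harvest
measurements (grain yield, culm and spike density, total biomass) by
ordinary least squares `y = a + bx` with the Pearson coefficient R and a
two-tailed Student-t test, `t = R sqrt(n-2) / sqrt(1-R^2)` with `n − 2`
degrees of freedom. P-values are reported both numerically and in the
discrete bins used in the original figures (<0.001 … <0.05, else N.S.).
Each pairing is run with all nine varieties and again excluding the modern
cultivars (PG, SV for durum; AX, AL for common wheat), whose breeding
history makes them outliers for biomass relationships. No multiple-testing
correction is applied, matching the original analysis; callers can apply
`p.adjust` to the returned p-values.

Because n = 9 is fully enumerable, the package includes an exact
permutation test of R (all 9! = 362 880 orderings; Monte-Carlo with a
plus-one correction above n = 9) as a model-free companion to the t-test.
On the headline stress-index/yield pairing the two agree to a few 10⁻⁴.
On mid-range (clearly non-significant) pairings the exact permutation
tail and the t tail can differ by around 0.01 — an inherent property of
discrete data at n = 9, not an implementation artefact — while agreeing
on every accept/reject decision at the 0.05 level; the test suite pins
both behaviours.

When reproducing the published analysis the inputs are the printed
2-decimal summary values, so reproduction tolerances are ±0.01 on
aggregated indices (the published maximum error) and bin-level on
significance. One printed claim is rounding-sensitive: recomputed from
the printed tables, the common-wheat `WSI_m`–biomass correlation lands at
p ≈ 0.052, marginally outside the 0.05 bound the original text groups it
under. The package reports the recomputed value and takes no side.

## Problem sizes and runtime

The full synthetic study (both species: 72 cells × 4 sessions × 10 frames
= 2 880 frames of 320 × 240) streams through segmentation in about
45 seconds on one core; the test suite uses the full durum half for the
end-to-end recovery check and smaller frame sizes elsewhere. Per-frame
memory is one 76 800-pixel raster; frames are discarded after
segmentation in streaming mode.

## Known limitations

* The WSI presumes positive Celsius temperatures; near- or sub-zero soil
  temperatures (winter acquisitions) make the normalisation ill-defined,
  and the package refuses them rather than extrapolating.
* Mean-of-peaks thresholding needs a visible valley; at class separations
  below roughly 4 within-class standard deviations the modes merge and
  the Otsu fallback, while deterministic, inherits the full overlap bias.
* Within-frame soil is assumed representative of "soil in proximity" to
  the crop; dedicated soil-reference regions are not modelled.
* The published dispersion values (±0.01 on WSI, ±0.03–0.05 on WCI) have
  an unstated estimation method; the package reports its own standard
  errors and does not try to reproduce them.
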
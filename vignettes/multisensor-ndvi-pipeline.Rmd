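---
title: "Gap-filled multi-sensor NDVI time series and crop classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gap-filled multi-sensor NDVI time series and crop classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenofuse)
```

## The problem

Optical satellite monitoring of cropland in cloudy temperate regions
rarely yields a clean seasonal NDVI record from any single sensor. In the
season this package emulates, more than half of all Sentinel-2 and
Landsat-8/9 acquisitions have over 20 % of their pixels masked by clouds,
cloud shadow, haze or snow, and truly cloud-free scenes cluster in a few
weeks. A third data source — 60 m daily NDVI composites of the Meteor-M
type, delivered already smoothed by the provider — fills temporal gaps but
at coarser resolution and with a systematic negative bias and an earlier
apparent seasonal maximum. phenofuse reconstructs per-pixel seasonal NDVI
curves from such gapped observations, harmonizes the three sensors on one
geographic 60 m grid, summarizes crop phenology, and classifies
crop/fallow classes with a random forest under leakage-safe grouped
evaluation.

Because the original imagery is not redistributable, the package is
organized around a synthetic scene generator with known ground truth; all
claims the test suite makes are claims about this generator plus the
published confusion matrices shipped as text fixtures.

## Pipeline and model

1. **Masking.** Sentinel-style scenes carry an SCL quality grid; codes
   0, 1, 3, 8, 9, 10, 11 are masked (code 2, dark-area pixels, is treated
   as valid — it is absent from the exclusion list, and we flag this
   reading explicitly). Landsat-style scenes carry a QA_PIXEL grid; only
   the clear-land value 21824 is kept. Masked pixels become missing
   values, never zeros, so fitting sees only valid observations. Scenes
   are tallied into masked-fraction bins `<5 %`, `5–20 %`, `20–50 %`,
   `>50 %`; bins are half-open on the left so "less than 5 %" is
   literally $[0, 0.05)$, and the last bin closes at 1 so the four bins
   partition $[0,1]$.

2. **Fitting.** Each pixel's valid NDVI observations $(t_i, y_i)$ are fit
   with a two-term truncated Fourier series
   $$f(t) = a_0 + a_1\cos(wt) + b_1\sin(wt) + a_2\cos(2wt) + b_2\sin(2wt).$$
   The five linear coefficients are profiled out exactly by linear least
   squares at any candidate frequency $w$, leaving a one-dimensional
   residual profile in $w$ that we minimize by golden-section refinement
   around the best local minima of a 12-point log-spaced grid over
   $w \in [2\pi/800, 2\pi/120]$ (one cycle per 120–800 days), with a
   seasonal prior at $2\pi/368$. This multi-start profiled solver is
   deterministic, needs no derivatives, and recovers noiseless series to
   machine precision. The fitted curve is evaluated at every integer day
   of the 176-day season (DOY 121–296), clamped to $[-1, 1]$, and reduced
   to 26 weekly anchors (DOY 121, 128, …, 296) by averaging the 7-day
   window $[a, a+6]$ (truncated at DOY 296).

3. **Meteor path.** Daily 60 m composites are *not* refit — they are
   already the product of provider-side local regression smoothing and
   carry no quality layer to drive a refit — so their weekly values are
   windowed means of the daily record (DOY 122–269), with interior gaps
   interpolated linearly between anchors and season ends extended from
   the nearest valid anchor.

4. **Harmonization.** The common grid is geographic (lon/lat) with pixel
   size $\text{resolution}/111000$ degrees (60 m → ≈ 0.00054°, the
   equatorial 1° ≈ 111 km conversion; latitude convergence is knowingly
   ignored, as this mirrors the upstream product definition). Weekly
   layers — already gap-filled, per the pipeline order — are resampled
   bilinearly at target cell centers. If a positively weighted neighbor
   is missing the output is missing; zero-weight neighbors are ignored,
   which makes resampling a grid onto itself the identity and keeps
   aligned nested grids (20/30/60 m sharing an origin) exact.

5. **Phenology.** Field series are unweighted means over the field's
   cells. NDVImax and DOYmax come from the daily reconstruction for
   fitted sensors (day precision; the weekly series is re-fit through its
   26 anchors to recover the daily curve) and from the weekly grid for
   Meteor (7-day precision). Ties take the earliest day. Bimodal classes
   are additionally summarized by early/late maxima split at DOY 210,
   which separates the reported first-maximum range (late June–July) from
   the second (late August–September); the split is configurable.
   Class summaries report the mean, a 95 % *t*-interval half-width (the
   published tables print "±" without defining it; we document this
   choice and do not claim to match those half-widths numerically), and
   the coefficient of variation in percent. Year-to-year comparisons use
   closed-form one-way ANOVA with Tukey HSD pairwise p-values from the
   studentized range (Tukey–Kramer standard errors under unequal n);
   zero within-group variance with unequal means reports F infinite,
   p = 0 by convention.

6. **Classification.** The default feature vector concatenates the 26
   weekly NDVI values of each available sensor (26 per sensor, 78 for the
   multi-sensor set). Training rows are filtered per class and feature by
   the interquartile rule $[Q_1 - 1.5\,\mathrm{IQR},\ Q_3 +
   1.5\,\mathrm{IQR}]$ with type-7 (linear interpolation) quantiles — the
   rule leaves the quartile convention open, so we document ours — and a
   row is removed if *any* feature is out of bounds. Train/test splitting
   and cross-validation operate on whole fields (groups), never pixels,
   preventing spatial leakage: the grouped 50/50 split greedily assigns
   shuffled fields per class toward the target row share, and the
   stratified group 3-fold CV deals each class's fields to the currently
   lightest fold. The classifier is a 50-tree random forest; remaining
   hyperparameters are the implementing library's defaults and are
   recorded in the run manifest. Accuracy is pixel-counted: overall
   accuracy is the confusion-matrix trace over its total (percent),
   per-class F1 is $TP/(TP + (FP+FN)/2)$, and F1mean is the unweighted
   class mean. Maps assign each field its modal predicted class, breaking
   ties by predicted-probability mass and then canonical class order
   (soybean, grain crops, buckwheat, perennial grasses, fallow).

## The synthetic landscape: what it emulates, and what not

The generator's defaults are the 2022 study conditions:

* **Fields.** ~200 rectangular fields of 2–3 cells per side aligned to
  the 60 m grid, separated by a one-cell buffer, with class counts in
  the 2022 cropped-area shares (soybean 62 %, fallow 20 %, grain 10 %,
  perennial grasses 4 %, buckwheat 4 %).
* **Curves.** Per-class seasonal maxima and their timing are sampled from
  truncated normals with the published 2022 means and coefficients of
  variation (soybean 0.88 at DOY 221; grain 0.77 at 192 with the
  season's large 15 % timing spread; buckwheat 0.88 at 196; fallow 0.84
  at 191; perennial grasses bimodal, 0.81 at 174 plus 0.78 at 265).
  Curve shapes are class-specific — a broad plateau for fallow, a sharp
  mid-summer peak for buckwheat, a narrow late season for soybean —
  following the qualitative reference-curve descriptions. The default
  family is the same truncated Fourier basis the fitter uses, so the
  noiseless closed loop is exact by construction and simulator error is
  not confounded with fitter error; a double-logistic family is provided
  for robustness experiments, and bimodal classes use a two-bump
  mixture.
* **Sensors.** Sentinel: 20 m, 61 scenes (~every 3 days, jittered),
  masked-fraction bins drawn with probabilities 8/5/11/37 of 61;
  Landsat: 30 m, 15 scenes, bins 2/1/5/7 of 15; Meteor: 60 m daily
  (DOY 122–269), no quality layer, additive bias −0.06 NDVI and peak
  shift −15 days (midpoints of the reported 0.05–0.08 and 10–20 day
  ranges). Observation noise is 0.02 NDVI per scene (0.01 for the
  smoothed Meteor product); within-field heterogeneity is a 0.02 NDVI
  per-cell offset shared across sensors (the publication gives no
  within-field variance, so this is a free parameter held at a
  realistic value).
* **Clouds.** Spatially coherent masks are produced by thresholding a
  bilinearly upsampled coarse Gaussian noise field at the quantile that
  realizes the drawn masked fraction exactly. We chose this over
  dilated random walks: identical spatial-coherence intent, exact
  fraction control, and far cheaper on large grids.

Not emulated: radiative transfer, topography, BRDF, atmospheric residuals,
georegistration error, irregular field shapes, and within-season
management events (mowing dates are only implicit in the bimodal grass
model). Passing tests therefore demonstrate internal consistency of the
method chain and calibrated statistical recovery — not performance on
real imagery, whose confusion structure is represented here only through
the published matrices shipped as fixtures.

## Numerical and design choices

* **Minimum observations.** `fit_fourier` refuses series with fewer than
  8 valid points by default (six parameters plus two). The *pipeline*
  floor is 6, the identifiability minimum: with the 2022 cloud
  distribution a 15-scene Landsat season averages ~7.9 valid
  observations per pixel, so a floor of 8 removes about half of all
  Landsat pixels — and, since a 60 m cell needs all four contributing
  30 m pixels, empties the harmonized Landsat layer almost entirely.
  At the floor the fit may interpolate its observations exactly;
  clamping to $[-1,1]$ bounds the damage, and the resulting noisier
  Landsat features are visibly the weakest single-sensor set in the
  classification tables, mirroring the real data-deficiency ordering.
* **Windows.** "Weekly sliding window" is implemented as a 7-day stride
  with the mean statistic (max is available as an option); stride and
  statistic are otherwise unspecified upstream.
* **Problem sizes.** The default study (200 fields, 100 × 100 cells,
  ~18 000 fitted pixels across Sentinel and Landsat) runs in well under
  a minute on one core; module tests use 25–40-field landscapes. These
  sizes were chosen so the full acceptance study — including a ten-seed
  replication of the multi-sensor-versus-single-sensor comparison —
  remains an interactive computation.
* **Determinism.** Every randomized stage takes an explicit seed; the
  pipeline derives per-stage seeds from one master seed, and reruns are
  bit-identical (the test suite asserts this).
* **Degenerate inputs.** Constant series short-circuit to an exact
  constant fit at the prior frequency; zero-IQR features collapse their
  bounds to the value itself, removing all non-equal rows (documented
  rather than special-cased); classes with under 4 training rows skip
  IQR filtering with a warning; a class represented by a single field
  makes grouped splitting fail loudly rather than leak.

## A worked run

```{r, eval = FALSE}
run <- run_pipeline(seed = 42, run_cv = TRUE)
sapply(run$cv_reports, function(r) r$pooled$oa)
run$split_reports$multi
head(run$phenology$sentinel)
```

The numbered scripts under `analysis/` execute this study step by step
(simulation, fitting, phenology, classification, published-matrix
recomputation) and write their tables under `results/`;
`scripts/acceptance.R` recomputes the headline quantities from scratch
into a single JSON file.

## Known limitations

* The geographic grid ignores latitude convergence (inherited, and
  documented, from the upstream product definition); distances east–west
  are therefore only nominal meters.
* Meteor series are never curve-fit, so their DOYmax resolution is the
  7-day anchor spacing.
* The IQR filter is applied feature-wise; a multivariate outlier that is
  marginally unremarkable survives it.
* The simulator's clouds are independent across scenes; real cloud cover
  is temporally autocorrelated, which would lengthen worst-case gaps.
* With 60 m cells and 2–3-cell field sides, mixed boundary pixels are
  absent by construction; real field borders would add label noise.
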
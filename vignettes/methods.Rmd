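---
title: "Methods: weighted arithmetic WQI, exceedance analysis, IDW surfaces and synthetic monitoring data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: weighted arithmetic WQI, exceedance analysis, IDW surfaces and synthetic monitoring data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aquaindex)
```

## The model

The weighted arithmetic WQI condenses a vector of physicochemical
measurements into one score by comparing each parameter to a regulatory
standard. Three quantities define it. The **quality rating**

$$q_i = 100\,\frac{v_i - v_{io}}{s_i - v_{io}}$$

maps the measured value $v_i$ onto a scale where the ideal value $v_{io}$
rates 0 and the standard permissible value $s_i$ rates 100. The **unit
weight** $w_i = k/s_i$ with $k = 1/\sum_i s_i^{-1}$ makes parameters with
stricter limits count more; the weights sum to 1 by construction. The index
is $\mathrm{WQI} = \sum_i q_i w_i / \sum_i w_i$.

The ideal values are 0 for every constituent except pH ($v_{io} = 7$,
neutral) and dissolved oxygen ($v_{io} = 14.6$ mg/l, the saturation
reference). Because DO's standard (8 mg/l) lies *below* its ideal, the rating
denominator is negative and under-saturated water correctly receives a
positive rating.

Key modelling assumptions: ratings are affine in the measured value;
parameters combine linearly (no interactions); and the standards table fully
determines both rating scale and weighting. The index is computed either per
sample or per ward — in the ward path the arithmetic mean of each parameter
over the ward's samples is formed first and the index is computed on the mean
vector, which is the convention for ward-level reporting (and differs from
averaging per-sample indices, since the two agree only because the index is
affine in each parameter; they diverge once values are missing unevenly).

### Grade bands

Published band tables print integer ranges (0–25, 26–50, …), which leave
non-integer scores such as 25.4 unassigned. We use half-open intervals with
inclusive upper bounds — excellent $(-\infty, 25]$, good $(25, 50]$, poor
$(50, 75]$, very poor $(75, 100]$, unsuitable $(100, \infty)$ — so every real
score receives exactly one grade. Negative scores are possible under signed
ratings (e.g. acidic pH below the ideal with nothing else deviating); they
classify as excellent and emit a warning, since a large negative rating is
itself a deviation worth the analyst's attention.

### Signed versus absolute ratings

The literal formula is signed: pH 5.5 rates $-100$ and *lowers* the index
even though acidic water is a deviation. We keep the signed form as the
default because it is the published formula, and offer `mode = "absolute"`
(ratings $100\,|v_i - v_{io}|/|s_i - v_{io}|$) for analysts who prefer
deviations in either direction to raise the score. The chosen mode is stored
on every result object.

### Missing data

The default policy is `strict`: the index over a 10-parameter standard is
only comparable to other 10-parameter indices, so a missing parameter is an
error naming the gap. `renormalize` recomputes the weights over the present
parameters (it does **not** rescale the full-table weights — the weights are
re-derived from the inverse-standard formula on the subset, preserving
$\sum w_i = 1$).

## Exceedance analysis

A value exceeds its permissible limit if it is above an upper-only limit or
outside a two-sided range (pH 6.5–8.5, DO 6.5–8 mg/l); deviation on either
side of a range counts. Bounds are inclusive-pass: a value exactly at the
limit does not exceed, a convention the source tables never adjudicate.
Summaries report per group (zone or ward) and parameter the count, min, max,
mean, sample SD ($n-1$ denominator — the monitoring-statistics convention;
population SD is not offered), exceedance count and percentage. Percentages
are rounded half away from zero to 2 decimals for display, with the
full-precision value kept in a parallel column; half-up rounding is what
published tables use, whereas R's default round-half-even would disagree on
exact ties.

## IDW interpolation

The value at an unsampled location is
$\hat z = \sum_i \lambda_i z_i$ with
$\lambda_i = D_i^{-a} / \sum_j D_j^{-a}$ over the $m$ nearest sampled points
(optionally restricted to a cut-off distance). Choices that the formula
leaves open:

* **Defaults** `power = 2`, `max_neighbors = 12`, no cut-off, planar metric.
  Power 2 is the near-universal default; 12 neighbours sits inside the
  customary 10–30 guidance. For a study extent of ~0.2° the planar
  approximation on raw degrees distorts the east–west scale by under 7%
  (cos 20°), which is immaterial for a weighting function; `haversine` is
  available for larger extents.
* **Ties** at the $m$-th neighbour distance are all included, so the
  neighbourhood may exceed $m$ but is deterministic and independent of point
  order.
* **Coincident points**: the weight formula is undefined at $D = 0$; a target
  coinciding with data returns the mean of the coincident values exactly
  (warning if they differ), the exact-interpolation limit.
* Predictions are convex combinations, hence bounded by the neighbour values;
  power 0 degenerates to the neighbourhood mean and large powers converge to
  nearest-neighbour assignment. These properties are asserted in tests.

Surfaces are evaluated at cell centres of a regular grid and written as ESRI
ASCII grids (`ncols/nrows/xllcorner/yllcorner/cellsize/NODATA_value` header,
row-major values, north row first). The format supports square cells only;
the writer refuses non-square grids rather than silently resampling.

## The synthetic-data generator

The generator emulates the study design the package targets: three municipal
zones with 21, 21 and 25 wards, five sampled locations per ward — 335 samples
— over the bounding box 20°12′–20°25′ N, 85°44′–85°55′ E. Each zone×parameter
cell of the built-in profiles carries the published min, max, mean and SD,
and draws come from a **normal distribution truncated to [min, max]**. Only
those four statistics are published; the truncated normal is the natural
family consistent with their roles (a central tendency, a spread, and hard
observed bounds). Truncation shifts both moments, so recovery tests compare
against the truncated distribution's closed-form mean and SD
(`truncnorm_moments()`, cross-checked against numerical integration), never
against the untruncated inputs.

Ward centroids are placed uniformly in the bounding box and the five samples
of a ward are jittered around their centroid with a normal SD of 0.004°
(~400 m, a plausible within-ward spacing), clamped to the box. Sampling is
inverse-CDF (`qnorm` of a uniform between the CDF values at the bounds), so
draws respect the bounds exactly and a fixed integer seed reproduces the
table bit-for-bit on any platform using R's default generator.

What the generator does **not** emulate: cross-parameter correlation (the
published statistics carry no covariance; hardness–TDS correlation in real
water is substantial), spatial autocorrelation of water quality along the
pipe network, temporal dynamics, and the exact empirical marginals of the
deposited raw data. Passing recovery tests therefore demonstrates that the
pipeline's statistics are correct for independently drawn truncated-normal
data — not that real supply-water data share that structure.

### Exceedance-count calibration

Marginal statistics do not pin down how many draws exceed a limit, but the
published south-east counts (EC 90 of 125, hardness 56, DO 19, pH 8) are
internally consistent with the design and serve as reproduction anchors. The
generator therefore offers a calibration mode: the requested number of
largest draws is spaced evenly in the interval between the limit and the
profile maximum, and the remaining draws are rescaled into the permissible
band only if any strayed past it. The remap preserves the rank order of the
draws and all bounds; for two-sided limits the non-exceeding draws are kept
inside the *two-sided* band (otherwise a draw pushed below the lower bound
would still exceed) and a `side` argument chooses which bound the exceeders
cross.

## Numerical choices

* Scores and summaries are kept at full double precision internally; only
  display columns are rounded (half away from zero, 2 decimals).
* Weight normalization holds to 1e-12 and the IDW brute-force equivalence to
  1e-12; the WQI oracle equivalence to 1e-9.
* `qnorm` round-off at extreme truncation quantiles is guarded by a final
  clamp to the bounds.
* Degenerate generator inputs: `min == max` yields a constant parameter;
  `sd = 0` with a non-degenerate range draws the clamped mean and logs a
  message.

## Problem sizes in the test suite

The suite exercises the weight-normalization property on 1,000 random
standards tables, IDW oracle agreement on random configurations of up to 50
points, Monte-Carlo moment recovery on 50,000 truncated-normal draws, and
parameter recovery on a 100× oversampled design (33,500 samples, every
zone×parameter cell within ±3 standard errors of the truncated-normal mean).
These sizes make sampling noise negligible relative to the tolerances while
keeping the suite fast.

## Known limitations

* Applying the literal formulas to the published zone-mean values yields
  scores in the 50–70 range ("poor"), whereas the source study reports only
  excellent/good grades for the same water. The study's per-ward index values
  are not reconstructible from its printed formulas and summary statistics —
  most plausibly different standard values or absolute ratings were used but
  not stated. The package reproduces the *published formulas* and anchors the
  published grade distribution through constructed score sets rather than
  pretending the two reconcile.
* Published north and south-west exceedance percentages imply denominators of
  ~103 and ~105 while the stated design gives 105 for both; only the
  internally consistent south-east figures (n = 125) are used as anchors.
* The index weights are dominated by BOD (unit weight 0.41 of 1) because of
  its strict 5 mg/l standard; this is a property of inverse-standard
  weighting itself, worth keeping in mind when comparing indices across
  standards tables.
* No unit conversion: measurements must already be in the standards table's
  units.
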
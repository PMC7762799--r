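---
title: "Methods: from colony images to conjugation-efficiency calls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from colony images to conjugation-efficiency calls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(conjscreen)
```

## The measurement principle

On a plate that is doubly selective for two non-interfering bacteriostatic
resistances, only transconjugants — recipient cells that have received the
conjugative plasmid from a donor — can divide. When a mixed
donor-plus-recipient population is pinned onto such a plate, the colony's
growth lag is the time to conjugate the plasmid plus the (fixed) time to
express its resistance gene. With the recipient genotype held constant,
variation in lag time across donor strains *is* variation in conjugation
time. `conjscreen` turns time-lapse colony intensity data from such plates
into strain-level conjugation-efficiency calls.

The pipeline has five computational stages, each exposed as ordinary
functions:

1. **Plate layout** (`build_screen_layout()`): a 1536-position grid
   (32 × 48) where the reference control mating occupies every fourth
   position — one per 2 × 2 block, 384 controls — and the remaining 1,152
   deposited populations are library matings (768, at 4 replicates per
   plate) plus donor-only / recipient-only negative controls (384).
2. **Image quantification** (`detect_grid()`, `measure_intensities()`,
   `calibrate_counts()`): per-colony background-subtracted intensities,
   converted to population counts.
3. **Curve analysis** (`smooth_curve()`, `find_flat_phase()`,
   `find_linear_phase()`, `extract_features()`): lag time and growth rate
   by flat/linear segmentation on the log2 scale.
4. **Screen statistics** (`normalize_plate()`, `aggregate_and_test()`):
   spatial normalization against interleaved controls, censoring,
   Wilcoxon + FDR hit calling.
5. **Validation calculators** (`mating_results()`,
   `efficiency_of_plating()`): liquid-mating conjugation frequencies from
   spotted dilution counts, and phage efficiency of plating.

A truth-tagged simulator (`simulate_curve()`, `simulate_plate()`,
`simulate_screen()`, `render_image_stack()`) generates synthetic screens at
the same design points, so every stage is testable without any external
data.

## Intensity calibration

Scanner intensities are converted to population counts with the fixed
quintic calibration

$$y = 2.128\times 10^{-2}x^5 + 1.023\,x^4 + 11.47\,x^3 + 25.62\,x^2,$$

where $x$ is the background-subtracted, summed colony intensity on the
acquisition system's calibrated scale. All coefficients are positive and
the lowest power is 2, so the conversion is strictly increasing and convex
on $x>0$ with $y(0)=0$; `invert_calibration()` inverts it numerically to
1e-12 relative tolerance (the synthetic renderer uses the inverse to decide
what intensity a colony of a given population must show). Both scales are
treated as opaque but internally consistent units: the data do not fix
absolute units for either, and nothing downstream depends on them because
all effects are ratios.

Grid detection projects the image onto each axis, matches a regular comb at
the format's pitch (plates are rigidly held, so the grid is regular up to
translation), and refines each line by an intensity centroid plus a linear
fit across the array. Detection runs once on the final, highest-contrast
frame and is reused for all frames. Per-cell background is the median pixel
of the cell box's border margin (width pitch/8, min 1 px), which makes
measurements exactly invariant to constant illumination offsets.

## Growth-curve segmentation

Curves are analyzed on the log2 population scale, where lag, exponential
growth and saturation appear as flat–linear–flat segments.

* **Smoothing** is locally weighted polynomial regression (degree 2,
  tricube weights) over a 9-point window, with truncated windows at the
  ends. The per-interval derivative $d_i = s_{i+1} - s_i$ is recomputed
  from the smoothed values only.
* **Flat phase**: the earliest run of at least 3 consecutive points with
  $-0.02 < d < 0.02$ that starts within the first quarter of the series.
  The $\pm 0.02$ band applies to the per-10-minute interval difference
  (about 0.12 log2 units/h); the derivative estimator and its time
  normalization are not uniquely determined by convention elsewhere, so
  both the band and the estimator are configurable in `curve_config()` and
  echoed into every output file. The flat phase must additionally sit near
  the curve's *starting* level (within 25% of the total rise): without this
  constraint, a colony that grows immediately and saturates early would
  have its saturation plateau mistaken for a lag phase.
* **Linear phase**: 5-point sliding windows over the region after the flat
  phase; the window with the largest increase seeds the segment, adjacent
  windows with slopes within 20% of the best are merged, and the line is
  refit over the merged segment. Ties go to the earliest window. The refit
  slope is the growth rate; below 0.05 log2/h the curve is called
  non-growing.
* **Lag** is the crossing of the flat level and the linear-phase line,
  $t^\* = (\text{level} - b)/m$, accepted when the linear phase starts
  after the flat phase ends and $t^\*$ lies between them. A curve with a
  linear phase but no initial flat phase "grows with no detectable lag"
  (`no_lag`, lag 0, as the doubly resistant positive control does); a
  curve with no linear phase is `no_growth` and is never assigned a finite
  lag.

**Noise-adaptive smoothing.** The flat-phase band is fixed, so the
derivative noise must be small relative to ±0.02. After the first 9-point
pass the residual log2 sd is estimated; curves noisier than 0.05 are
re-smoothed with a 21-point window. Clean curves keep the short window,
which resolves lags as short as 1 h; noisy curves trade that resolution for
a quiet derivative. At a per-point log2 noise sd of 0.1, lag RMSE over 500
simulated curves (lags 2–10 h, rates 0.8–2 doublings/h) is about 0.08 h,
versus about 1.6 h with the fixed 9-point window — the fixed window loses
the flat phase entirely on ~11% of noisy curves. On noise-free curves over
a lag (1–12 h) × rate (0.5–2) grid, recovery is exact to one 10-min
sampling interval in 36/36 cases and rates are recovered within 2%.

**QC** is fully automated (thresholds in `curve_config()`, echoed into
outputs): positions whose initial smoothed population falls below the
deposition floor are `mispinned` (failed pinning, the dominant failure mode
of robotic deposition); curves whose smoothed log2 trace falls more than 1
unit below its running maximum are `rejected` as non-monotone artifacts.
The drawdown rule, rather than a single-step bound, is used because
smoothing spreads a sharp raw drop across the window.

## Interleaved-control normalization and hit calling

Every fourth position carries a genetically identical control mating, so
each experimental position has controls within its immediate neighbourhood.
The local reference of a position is the **median lag of its k = 4 nearest
controls** (Euclidean grid distance; ties broken by (row, col); a control
is left out of its own neighbourhood). The per-replicate effect is
$e = \log_2(\text{lag}/\text{reference})$; positive effects mean delayed
conjugation. Neither the neighbourhood size nor the averaging statistic is
canonical — the interleaved design guarantees 4 controls within the
surrounding few rows and columns, and the median is robust to a single
failed control — so both are configurable.

Because the same smooth spatial field (temperature, illumination, agar
thickness) multiplies controls and experimentals alike, the ratio cancels
it: with a synthetic lag field of CV 9% and zero true effects, normalized
effect spread changes by under 2% relative to a flat plate, and the
residual field signature in noise-free effects is below 0.05 log2 units
(the field's local curvature across a 3×3 neighbourhood).

**Censoring.** Replicates with no measurable growth are assigned
$e = 2$ exactly — a lag at least 4× the local control. Measured finite
effects are never altered; a genuine 8× lag reports $e = 3$. (Capping
measured effects at 2 is available but off by default: the censoring rule
exists to encode non-growth, not to clip the scale.) Zero-lag replicates
in a mating context are given the minimum measurable lag of one sampling
interval, keeping the ratio finite.

**Per-strain aggregation**: median effect (ranking; rank 1 = most
delayed), SEM, one-sample Wilcoxon signed-rank test against zero, and
Benjamini–Hochberg FDR across strains. The Wilcoxon implementation uses
the exact signed-rank null when there are no zeros or ties (n ≤ 25), exact
sign-flip enumeration with Pratt ranks when zeros are present and the rest
are few and untied, and a normal approximation with continuity, tie and
zero corrections otherwise; it is checked against exhaustive enumeration
for all n ≤ 10. Two-sided p-values are the default, with one-sided
available for the directional question (delayed conjugation). Gene-set
enrichment is the one-sided hypergeometric tail; screen concordance is the
squared Pearson correlation of matched strain medians; the growth-rate
confound check correlates relative growth rate with relative lag.

## The simulator and what it does (not) emulate

The canonical synthetic curve is piecewise linear in log2 — exactly the
shape the segmentation assumes — with optional C¹ quadratic corner
rounding (`smooth_span_h`) to probe robustness against less idealized
transitions. Defaults mirror the screen's study conditions:

| parameter | default | meaning |
|---|---|---|
| base lag | 5.46 h | control mating lag at 30 °C |
| spatial field CV | 0.09 | smooth low-order surface on lag, per plate |
| growth rate | 1.5 log2/h | exponential-phase slope |
| n0 / capacity | 2×10⁴ / 2×10⁶ cells | deposited and saturated population |
| sampling | 10 min × 24 h | 145 points per curve |
| replication | n = 8 (4 × 2 plates) | primary design; n = 18 (6 × 3) secondary |
| effect sd | 0.23 | strain effect distribution, log2 scale |
| replicate lag noise | 0.05 log2 | per-replicate lag scatter (lag-level path) |

Replicate noise magnitudes for single curves are not pinned down by any
external reference; the defaults were chosen once so that control lag
variability lands near the 9% CV scale and were not revisited. The
simulator reproduces the observable growth phenotype only: it does not
model conjugation mechanism (pilus dynamics, plasmid copy number),
donor-strain fitness differences, antibiotic hypersensitivity, or
day-to-day batch effects. Consequently, passing recovery tests demonstrate
that the *computational* pipeline is unbiased and calibrated under the
stated noise model — not that real plates are free of the biological
confounds that require the validation assays (liquid mating, phage
plating) in the first place. Two screens simulated from shared truth agree
with R² ≈ 0.98 under these defaults; observed between-screen concordance
in real data is lower because biological replication noise exceeds the
modelled measurement noise.

Mispinning is modelled as an initial population below the detectability
floor, non-growing strains as capacity = n0. Every random step takes an
explicit integer seed; identical seeds give bit-identical datasets.

## Numerical and design choices

* Coordinates are 0-based (row, col), row 0 top-left, matching image
  row-major order; all files use this convention.
* The control position inside each 2 × 2 block is block-local (1, 1) (odd
  row, odd col) by default and configurable
  (`control_block_offset`).
* Zeros are floored at 1 cell before log2, preserving the shape of
  non-growing curves without −∞.
* The linear-phase crossing falling *before* the flat phase start is
  reported as `no_lag` (indistinguishable from growth since the first
  observation); a crossing beyond the linear phase end is reported as
  `no_growth`. Both are degenerate and rare.
* Titer estimation uses the most dilute dilution whose mean spot count
  falls in a countable band of 3–30 colonies per 10-µl spot (standard
  small-spot countability; configurable). Technical replicate spots are
  averaged before titer computation; biological replicates are kept
  separate through to the one-sided Welch t-test (pooled-variance Student
  optional).
* The statistics-level simulator path (`level = "lag"`) generates
  extracted lags directly and is used for calibration studies that need
  hundreds of screens; the curve-level path exercises the full extractor.
  Problem sizes in the test-suite calibration studies: 200 null screens of
  500 strains × n = 8 for FDR control; 5 screens of 500 strains (100 true
  2×-lag mutants, replicate sd 0.2) for power; 500 curves for noisy lag
  recovery; a full 1536 plate at 3 time points for the image round trip.

## Known limitations

* Lag resolution is bounded by the sampling interval (10 min) and, for
  noisy curves, by the wide smoothing window; lags shorter than ~1 h are
  only resolvable on clean curves, and shorter-than-control lags are
  intrinsically hard to measure in this design.
* Grid detection assumes a full array with visible colonies in a majority
  of rows and columns of the detection frame; sparse plates should supply
  geometry explicitly via `grid_geometry()`.
* The Wilcoxon normal approximation is used above n = 25 or with ties;
  p-values there are approximate (checked to ~5% against the exact tail).
* Enrichment treats the annotation table as given; it does not fetch or
  curate gene-set membership.
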
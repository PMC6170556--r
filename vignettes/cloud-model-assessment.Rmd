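---
title: "Assessing air quality with normal cloud models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing air quality with normal cloud models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aircloud)
```

## The model

A month of daily concentrations of one pollutant is noisy in two distinct
ways: the values themselves scatter (randomness), and the boundary of a
verbal grade such as "Moderate pollution" is not sharp (fuzziness). The
normal cloud model carries both in three numbers:

* **Ex** — the expectation, the most representative concentration of the
  concept;
* **En** — the entropy, the spread of concentrations the concept accepts;
* **He** — the hyper-entropy, the uncertainty of `En` itself, visible as
  the thickness of a rendered cloud.

A *cloud drop* is a sampled pair (x, membership). The **forward
generator** draws, per drop, an entropy realisation `En' ~ N(En, He^2)`,
then `x ~ N(Ex, En'^2)`, and evaluates the Gaussian membership
`mu = exp(-(x - Ex)^2 / (2 En'^2))`. Because `En'` changes from drop to
drop, the membership of a fixed concentration is a distribution, not a
number — that is the model's way of holding fuzziness and randomness at
once. The **backward generator** is the moment estimator used for data:

* `Ex` = sample mean,
* `En = sqrt(pi/2) * mean(|x - Ex|)` (first absolute central moment,
  scaled for the normal law),
* `He = sqrt(|S^2 - En^2|)` with `S^2` the n−1 sample variance.

We implement the first-order absolute-moment variant exactly as used in
this application area, not the fourth-moment variant found elsewhere in
the cloud-model literature. The absolute value under the square root
guards against sampling fluctuation driving `S^2 - En^2` negative; when
the clip fires the returned model carries `variance_clipped = TRUE`.

## Standard clouds and classification

Each grading level of a pollutant is a concentration band `[Cmin, Cmax]`
from the regulatory table (GB 3095-2012 / HJ 633-2012; five levels from
Good to Heavily Polluted). Its *standard cloud* is the closed form

    Ex = (Cmin + Cmax) / 2,  En = (Cmax - Cmin) / 6,  He = k * En

— the band midpoint, a 3-sigma spread convention, and a hyper-entropy
ratio `k` (default 0.1; conventionally at most one third, and values above
that warn). An assessed cloud is compared with level `j`'s standard cloud
by

    lambda_j = exp(-(Ex - Ex_j)^2 / (2 En_j^2)),

and the level with the largest `lambda` is the quantitative result (the
maximum membership principle). Alongside it we report a *qualitative*
result: the pair of levels whose standard expectations bracket the
assessed expectation, which reproduces narratives like "between Moderate
and Lightly Polluted" deterministically instead of by reading a picture.

```{r}
res <- assess_month(shenyang_nov2016())
res
```

## Tunable parameters

| parameter | meaning | default | notes |
|---|---|---|---|
| `k` | hyper-entropy ratio of standard clouds (dimensionless) | 0.1 | at most 1/3; only affects rendering thickness, not classification |
| `rho` | grey relational resolution coefficient | 0.5 | the conventional value; damps the max-distance term |
| `n_drops` | drops per rendered cloud | 1000 | rendering only |
| seeds | every stochastic operation takes an explicit integer seed | — | estimation, classification, AQI and GRA involve no sampling at all |

## The AQI stage

Each day's individual index (IAQI) per pollutant is the exact piecewise
linear interpolation of its concentration on the breakpoint table; the
day's AQI is the maximum IAQI, with the attaining pollutant recorded as
dominant. Band membership is half-open, `(BP_Lo, BP_Hi]` with 0 in band 1,
so a concentration exactly at a breakpoint maps to the index breakpoint
uniquely. We apply **no integer ceiling** to the IAQI: the regulation's
rounding is a reporting convention, and exact interpolation is the variant
consistent with downstream cloud estimation on the index scale (and the
one this package's own results are stated in). Concentrations above the
top breakpoint extrapolate linearly on the last segment and are flagged
`above_scale` rather than clamped — no information is destroyed, and the
flag propagates to the daily table. The CO column of the grading table is
interpreted in mg/m³ (the only unit under which the band values 2–36 and
real CO monitoring data are mutually consistent).

The 30 daily AQI values are then treated exactly like a pollutant series:
backward cloud, classification on the index-scale standard clouds.

## Grey relational cross-check

As an independent classifier, grey relational analysis takes the monthly
expectation per indicator (vector `a`) and the standard-cloud expectations
per level (matrix `b`), normalises both by the level-1 expectations so
units cancel, and scores each (level, indicator) cell by

    xi_ij = (Dmin + rho * Dmax) / (|d_j - f_ij| + rho * Dmax),

with `Dmin`/`Dmax` the global extremes of the distances over the whole
matrix (per the formula's double subscript — not per column). The level
attaining the column maximum is the GRA level; the pipeline reports the
count of indicators on which GRA and cloud levels agree. If every distance
is zero the matrix is degenerate; all coefficients are set to 1 and
flagged. Ties — in GRA and in cloud classification alike — break toward
the more severe level, the protective choice for a health-advisory
context.

## Synthetic data

Monthly raw series beyond the packaged November 2016 month are emulated by
a log-normal generator: on each day of month `m`,

    x ~ Lognormal(log(baseline) + amplitude * cos(2 pi (m - phase)/12), spread^2).

Defaults describe a northern Chinese industrial city with coal-fired
winter heating: baselines (PM2.5 55, PM10 95, SO2 40, CO 1.0 mg/m³, NO2
42, O3 75), log-spreads 0.25–0.50 chosen to match the coefficient of
variation of the packaged month (PM2.5 sd/mean ≈ 0.5), winter-peaking
PM2.5/SO2/NO2 (phase January, log-amplitudes 0.45/0.80/0.30),
summer-peaking O3 (phase July, 0.55), and season-flat PM10/CO
(amplitude 0). The generator reproduces seasonal *level* trajectories and
distributional shape; it does **not** emulate day-to-day autocorrelation,
cross-pollutant correlation (real PM2.5 and PM10 are strongly coupled), or
episodic smog events, so passing pipeline tests on synthetic months shows
the machinery is sound, not that real data will be as well behaved.

## Numerical choices and degenerate inputs

* Non-positive `En'` draws in the forward generator (possible whenever
  `He > 0`) are resampled, not truncated — truncation would bias drops
  toward `Ex`; the rejection count is reported.
* A zero-entropy model describes a crisp constant; forward generation
  returns a flagged degenerate sample (all drops at `Ex`, membership 1)
  rather than erroring, since constant monitoring data is legal.
* Similarity against a zero-entropy *standard* cloud is an error — the
  grading band would have zero width.
* Classification ties break toward the higher level; the argmax is
  invariant to any positive rescaling of the similarity vector.
* Similarities are reported at full precision for all levels; published
  reports often print distant levels as 0, meaning below print precision.
* Rendered cloud pictures clamp the horizontal axis at 0: concentrations
  are physically non-negative even when a large `En` pushes sampled drops
  below zero.

## Problem sizes

The packaged worked example is the 30-day November 2016 Shenyang month;
the level-trajectory example uses the twelve published monthly clouds.
Property tests use 100 000 drops for the forward–backward round trip
(recovery of `Ex` and `En` within 2%, `He` within 15% — `He` is a
second-order characteristic and its moment estimator is intrinsically
noisier) and 10–20 random replicates for matrix properties. Everything is
deterministic except forward generation and the synthetic generator, both
seeded.

## Known limitations

* Daily summary values are taken as given; no O3 8-hour/1-hour averaging
  or annual-vs-24-hour standards distinction.
* Five grading levels only; beyond-scale AQI (above 300) is flagged, not
  given the "Severely Polluted" label of the extended index.
* The similarity compares expectations only (scaled by the standard
  entropy); two assessed clouds with equal `Ex` but different `En` or `He`
  classify identically. The entropy and hyper-entropy speak through the
  qualitative picture and the reported characteristics, not the level.
* Normal (Gaussian) clouds only — no half or trapezoidal clouds, no
  multi-dimensional clouds.
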
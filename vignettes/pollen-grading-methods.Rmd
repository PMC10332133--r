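---
title: "Methods: from pollen deposition surveillance to a graded warning scale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from pollen deposition surveillance to a graded warning scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pollenscale)
```

## The problem

*Artemisia* (mugwort) pollen is a dominant late-summer aeroallergen in
northern-Chinese cities. Passive gravitational (Durham) samplers at a few
urban monitoring stations yield daily deposition counts in grains/1000 mm²,
and allergy clinics record the daily number of symptomatic patients with
positive *Artemisia*-specific IgE. `pollenscale` turns these two daily series
into a five-level deposition grading scale: each level is a deposition
interval annotated with the expected number of *additional patients per
one-grain increase* in deposition, so that a forecast deposition value maps
directly to a clinically interpretable warning grade.

## The model and the pipeline

The analysis chain is:

1. **City averaging.** The city-level daily deposition is the arithmetic
   mean over the stations reporting that day (`average_stations()`).
   Station-days that did not report are dropped from that day's mean, not
   imputed.
2. **Season detection.** For each year, the pollen season runs from the
   first day on which cumulative deposition reaches 2.5% of the annual
   total to the first day it reaches 97.5% (`detect_season()`). The "first
   day reaching the fraction" (≥) convention is used; a strict-inequality
   convention would differ by at most one day.
3. **Exposure windows.** Deposited grains retain reactive allergen for
   days, so the exposure metric is a trailing k-day moving average: the
   mean of the current and previous k−1 days (`moving_average()`). The
   first k−1 days of a series are missing rather than partially averaged,
   so every windowed value is a mean of exactly k days.
4. **Eligible pairs.** Modelling pairs (windowed deposition, same-day
   patient count) keep only in-season, non-rest-day dates with both values
   present (`select_samples()`). Rest days are weekends plus a configurable
   holiday list; hospital throughput differs on those days, which would
   bias the counts.
5. **Window selection.** Spearman rank correlation between patient counts
   and each candidate window (1–4 days by default); the window with the
   largest rho is chosen, ties going to the shorter window because less
   smoothing is the more conservative choice (`select_window()`).
6. **Dose–response fit.** Least squares for the shifted-logarithm curve

   $$f(x) = a\,\ln(x + c) + d,$$

   with derivative $f'(x) = a/(x+c)$: the expected additional patients per
   one-grain increase at deposition $x$ (`fit_log_curve()`, `derivative()`).
   The concave log shape captures the observed saturation: patient numbers
   rise steeply at low deposition and slow at high deposition.
7. **Thresholds.** Two basic series: (i) the 25th/50th/75th percentiles of
   the windowed deposition distribution and (ii) the deposition values at
   which 25%/50%/75% of all patients have cumulatively appeared when days
   are sorted by ascending deposition (`threshold_set()`). Because the
   lowest patient-quantile threshold misses the early season, the 25th
   deposition percentile is substituted as a new minimum threshold with a
   nominal 10% patient fraction whenever it lies below the 25%-patient
   threshold (`substitute_minimum()`).
8. **Scale.** The four thresholds $T_1<T_2<T_3<T_4$ partition the axis into
   five right-closed levels $(0,T_1], (T_1,T_2], (T_2,T_3], (T_3,T_4],
   (T_4,\infty)$; each level's patient-increment band is the interval of
   $f'$ values it spans, with edges $f'(T_i)$ (`build_scale()`,
   `classify()`).

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| season bounds | 0.025 / 0.975 | cumulative fraction | conventional 95%-mass season definition |
| window candidates | 1–4 | days | allergen persistence of settled grains is a few days |
| percentile fractions | 0.25/0.50/0.75 | — | quartiles of the exposure distribution |
| patient fractions | 0.25/0.50/0.75 | — | quartiles of the cumulative patient mass |
| minimum substitution fraction | 0.10 | — | nominal fraction attached to the early-season threshold |
| threshold rounding | half-up to integer | grains/1000 mm² | published-style scales use whole grains (10.5 → 11); full precision kept alongside |
| report precision | truncate to 2 decimals | — | truncation, not rounding: 0.4265 is reported as 0.42 |

## The synthetic-data generator

`generate_study_dataset()` emulates a three-year, four-station urban
surveillance design:

* **Seasonal shape.** A Gaussian bump in day-of-year per year — the
  simplest unimodal shape compatible with seasons that start on different
  days yet end consistently in mid-September. Defaults place the peaks in
  mid-to-late August with annual city totals of 4845, 3017 and 3008
  grains/1000 mm² and spreads of 17, 10 and 12 days across the three years.
* **Station noise.** Independent multiplicative lognormal noise with unit
  mean and CV 0.2 per station-day, preserving non-negativity; with CV 0 the
  city-mean annual sum equals the configured total exactly.
* **Patient counts.** Poisson draws around
  $\mu = \max(0, a\ln(x_w+c)+d)$ of the 3-day trailing city-mean
  deposition, with the published coefficients $a=8.33$, $c=8.53$,
  $d=-13.85$ as defaults. Counts are non-negative integers with no
  obvious overdispersion mechanism in scope, so Poisson is the natural
  minimal choice.
  Whether records are new cases or visits is unspecified in the source
  material; the generator treats them as independent daily counts.
* **Seeding.** One master seed is split into named substreams (pollen per
  year, patients per year), so either part can be regenerated
  independently and byte-identical CSVs result from equal seeds.

What the generator does **not** emulate: meteorological covariates (rain
suppresses deposition and symptoms), medication-use damping of counts at
high exposure, day-of-week patterns in care-seeking beyond the rest-day
exclusion, and reporting gaps. Passing tests on synthetic data therefore
show that the pipeline recovers the structure it assumes — not that real
surveillance data satisfy those assumptions.

## Numerical choices

* **Fitting.** Given the shift $c$, the curve is linear in $(a, d)$, so the
  fit profiles $c$ over a log-spaced grid ($10^{-2}$ to $10^{3}$, 121
  points), solves the inner linear least squares in closed form at each
  grid point, and polishes the best grid point with Brent refinement on
  $\log c$. This sidesteps the initialization sensitivity of a joint
  3-parameter nonlinear search. The loss is unweighted least squares on
  counts, consistent with reporting an $R^2$.
* **Degenerate inputs.** A constant patient series yields a flagged flat
  fit ($a=0$, $R^2=0$); a constant exposure series makes the rank
  correlation undefined and that candidate window is flagged rather than
  fatal; an all-zero pollen year raises a no-season error.
* **Patient-quantile thresholds** are computed from the empirical
  cumulative patient distribution over exposure-sorted pairs, not by
  inverting the fitted curve: the sorting construction is the operational
  definition, and it needs no parametric assumption. Curve inversion can be
  emulated by applying `predict()` to candidate thresholds if desired.
* **Interval conventions.** Deposition percentiles use linear
  order-statistic interpolation (R type 7). Scale levels are right-closed —
  an upper boundary belongs to the lower level — and $x = 0$ is outside
  every level. Classification is monotone in $x$ by construction.
* **c is weakly identified.** When the exposure range is narrow, very
  different $(a, c, d)$ triples produce nearly identical curves over the
  data range; $a$ and $d$ are recovered much more precisely than $c$. The
  parameter-recovery experiment in the test suite (25 replicates of
  $n = 500$ Poisson observations over a lognormal exposure distribution
  matched to realistic 3-day-mean quartiles) checks median relative errors
  of 15% for $a$ and $d$ only, with a lenient 50% for $c$.

## Window identifiability — a known limitation

Adjacent candidate windows of a smooth seasonal series are correlated above
0.95, so their Spearman correlations with the same patient series differ
only in the second or third decimal. At single-clinic count levels
(Poisson noise around means of roughly 0–35 patients/day) and a 3-year
design (~110 eligible pairs), the argmax over windows is therefore
unstable: the window-recovery experiment in the test suite, which generates
50 independent synthetic studies at the default design and re-runs the
selection, finds the generating 3-day window chosen in only a minority of
replicates, with 2- and 4-day windows close behind — exactly the
near-tie pattern seen in real correlation tables of this kind. With the
count noise switched off the selection recovers the generating window
deterministically (also tested). Users should read the chosen window as "a
short multi-day window clearly beats the raw daily series", not as a sharp
identification of k, and should prefer external (biological) grounds when
adjacent windows are statistically tied.

## Problem sizes used by the test suite

Monte-Carlo checks use 20–25 replicates (generator mean recovery,
parameter recovery at $n=500$) and 50 replicates for selection stability on
the default 3-year/4-station design; these sizes keep the full suite under
a minute of simulation while leaving Monte-Carlo error well inside the
asserted tolerances.

## Other limitations

* Gravitational deposition is not volumetric concentration; no conversion
  is attempted, and scales derived from one sampler type do not transfer
  to the other.
* The scale is single-taxon; co-circulating allergens would need their own
  scales.
* No uncertainty intervals are attached to $(a, c, d)$ or to the
  thresholds; the source methodology reports none, and bootstrap intervals
  would be a natural extension.
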
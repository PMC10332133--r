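# pollenscale

Graded pollen-exposure warning scales from daily surveillance data.

## What it is for

Urban pollen monitoring networks measure daily *deposition* — grains
settling per 1000 mm² of a passive (Durham) sampler — at a handful of
stations, while allergy clinics count the daily number of symptomatic,
allergen-sIgE-positive patients. For a strongly allergenic taxon such as
late-summer *Artemisia*, aerobiologists and allergists want those two
series turned into a small, interpretable warning scale: "at this
deposition level, how fast is the patient load growing?"

`pollenscale` implements that full analysis for anyone working with daily
pollen and patient-count series: city averaging over stations, pollen
season detection by cumulative 2.5%/97.5% bounds, trailing moving-average
exposure windows, Spearman-based window selection, a shifted-logarithm
dose–response fit, empirical threshold derivation, and a five-level
grading scale. A synthetic-data module generates realistic multi-year,
multi-station datasets so the whole pipeline runs and is tested without
any external data.

## The model

Daily patient counts grow logarithmically with the k-day trailing mean
deposition x:

    f(x) = a·ln(x + c) + d        f′(x) = a/(x + c)

f′(x) is the expected number of *additional patients per one-grain
increase* in deposition. Four thresholds T₁ < T₂ < T₃ < T₄ — the 25th
deposition percentile plus the depositions at which 25%, 50% and 75% of
all patients have cumulatively appeared — partition the axis into five
right-closed levels `(0,T₁] … (T₄,∞)`, each annotated with the band of
f′ values it spans.

## Worked example

```r
library(pollenscale)

study  <- generate_study_dataset(study_design(), seed = 1)
report <- run_pipeline(study$pollen, study$patients, study$calendar)
report$window_selection
#> Exposure-window selection (Spearman rho vs. patient counts)
#> # A tibble: 4 × 6
#>   window   rho  p_value     n significant_01 flagged
#>    <int> <dbl>    <dbl> <int> <lgl>          <lgl>
#> 1      1 0.592 7.77e-12   111 TRUE           FALSE
#> 2      2 0.602 2.73e-12   111 TRUE           FALSE
#> 3      3 0.600 3.30e-12   111 TRUE           FALSE
#> 4      4 0.609 1.32e-12   111 TRUE           FALSE
#> Chosen window: 4 day(s)
report$fit
#> Shifted-log dose-response fit: f(x) = a*ln(x + c) + d
#>   a = 6.582, c = 7.031, d = -6.205
#>   R-squared = 0.393  (n = 111)
```

The 111 eligible pairs are the in-season, non-rest-day dates; all four
candidate windows correlate strongly and nearly equally with the counts —
adjacent smooth windows are rarely sharply distinguishable (see the
methods vignette). The fitted report ends in the grading scale:

```r
report$scale
#> Pollen deposition grading scale (additional patients per one-grain increase)
#>  Level Deposition interval Patient increment
#>      1             (0, 38]             ≥0.14
#>      2            (38, 44]      [0.12, 0.14)
#>      3            (44, 77]      [0.07, 0.12)
#>      4           (77, 101]      [0.06, 0.07)
#>      5            (101, ∞)             <0.06
```

A scale can also be built directly from known coefficients and
thresholds, e.g. the published Beijing *Artemisia* fit:

```r
fit <- dose_response_fit(a = 8.33, c = 8.53, d = -13.85)
build_scale(c(11, 27, 59, 119), fit)
#> Pollen deposition grading scale (additional patients per one-grain increase)
#>  Level Deposition interval Patient increment
#>      1             (0, 11]             ≥0.42
#>      2            (11, 27]      [0.23, 0.42)
#>      3            (27, 59]      [0.12, 0.23)
#>      4           (59, 119]      [0.06, 0.12)
#>      5            (119, ∞)             <0.06
classify(build_scale(c(11, 27, 59, 119), fit), 80)
#> [1] 4
```

Reading: in level 1 every extra grain of 3-day-mean deposition brings at
least 0.42 extra patients per day; past 119 grains/1000 mm² the increase
has slowed below 0.06. A forecast deposition of 80 lands in level 4.

`tidy()`, `glance()` and `autoplot()` methods are provided for fits,
window selections and scales; `write_study_csv()`/`read_*_csv()` handle
the CSV interchange formats.

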
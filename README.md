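# codatime

Compositional data analysis of the 24-hour day against cognitive outcomes
in older adults.

A day is an exhaustive, mutually exclusive split of 1440 minutes into
sleep, sedentary behaviour (SB), light physical activity (LPA) and
moderate-to-vigorous physical activity (MVPA). Because the four durations
are constrained to a constant sum, they carry only *relative* information
and cannot be entered jointly into an ordinary regression — the design is
perfectly collinear. `codatime` implements the standard compositional
(CoDA) treatment of this problem for time-use epidemiology, wrapped in a
reproducible simulate-and-analyse pipeline: wrist-accelerometry epoch
processing, isometric log-ratio regression with behaviour-context
moderators (TV watching, recreational physical activity, sleep quality),
marginality-respecting type II F-tests with backward selection and
within-model Benjamini–Hochberg FDR adjustment, and one-for-remaining
time-reallocation prediction curves. A synthetic-cohort generator supplies
data with the statistical structure the analysis assumes, so every stage
is testable without access to participant-level data.

The intended audience is researchers in physical-activity and cognitive
ageing epidemiology who want the full analysis chain as tested,
composable functions rather than a one-off script.

## The model

A composition `x = (x_sleep, x_SB, x_LPA, x_MVPA)` closed to 1440 min is
mapped to three pivot (isometric log-ratio) coordinates under the
sequential binary partition (sleep, SB, LPA, MVPA):

```
z_k = sqrt((4-k)/(4-k+1)) * ln( x_k / gmean(x_{k+1}, ..., x_4) ),  k = 1, 2, 3
```

so `z1` contrasts sleep against the geometric mean of the waking
behaviours, `z2` contrasts SB against the two activity intensities, and
`z3` is the LPA:MVPA balance. The outcome model is ordinary least squares

```
y = b0 + b' z + g' C + sum_m (d_m' z) 1[moderator m level] + e
```

with covariates `C` (age, sex, site, education, smoking status),
moderator main effects, and composition × moderator interaction blocks.
All three coordinates enter together; the composition is tested as a
joint 3-df block. Backward selection removes, in order: (i)
non-significant interaction blocks (largest type II p first), (ii) the
composition block (only after all interactions are gone), and then (iii)
tests the remaining covariates collectively. P-values within each final
model are BH-FDR adjusted. Reporting per-behaviour associations uses
*pivot rotation*: refitting under the partition that places each
behaviour first and reading off the first coordinate's coefficient — that
behaviour "relative to the remaining three".

Accelerometry inputs are 1-min epoch values in g-min: non-wear is any run
of ≥ 60 min at ≤ 25 g-min; waking worn epochs are SB (≤ 48), LPA
(48–93], MVPA (> 93); a valid day has ≥ 10 waking worn hours, and a
participant needs ≥ 3 valid weekdays plus ≥ 1 valid weekend day.

## Worked example

```r
library(codatime)

res <- run_pipeline(pipeline_config(seed = 1))
res$eligibility
#> Eligibility accounting
#>   enrolled:                       426
#>   removed, invalid accelerometry: 21
#>   removed, missing covariates:    21
#>   final analysis sample:          384
```

The simulated enrolment roster of 426 loses 21 participants to the
accelerometry valid-week rule and 21 to missing covariates, leaving the
analysis sample of 384. The sample centre (compositional mean — closed
geometric means) and its ternary percentages:

```r
comp <- compositional_mean(as.matrix(res$analysis[, tu_parts()]))
round(comp, 1)
#> sleep    sb   lpa  mvpa
#> 505.0 661.9 183.9  89.3
round(amalgamate_to_ternary(comp)$percent, 1)
#>       sleep sb pa
#> sleep  35.1 46 19
```

i.e. roughly 35% of the day asleep, 46% sedentary and 19% active.
Backward selection for the processing-speed outcome (this realisation
drops all three interaction blocks, then the composition block):

```r
res$study$speed$trace
#>   step action                      term        p
#> 1    1 remove    composition:tv_tertile 0.787870
#> 2    2 remove composition:sleep_quality 0.396227
#> 3    3 remove     composition:recpa_cat 0.119208
#> 4    4 remove               composition 0.536428
#> 5    5   keep                covariates 0.000112
```

and the final-model type II table with within-model FDR:

```r
res$study$speed$term_table
#>            term       F df1 df2        p    p_adj
#> 1           age 23.6637   1 372 1.70e-06 1.36e-05
#> 2           sex  0.0525   1 372 8.19e-01 8.19e-01
#> 3          site  1.9750   1 372 1.61e-01 3.22e-01
#> ...
```

A one-for-remaining reallocation curve (here MVPA at the compositional
mean, global-cognition model, 15-min steps):

```r
head(res$curve, 4)
#>   delta predicted   lwr   upr
#> 1   -60     95.68 93.76 97.61
#> 2   -45     95.82 94.39 97.25
#> 3   -30     95.92 94.76 97.08
#> 4   -15     96.00 94.96 97.04
```

Each row is the predicted outcome when that many minutes are moved into
(positive delta) or out of (negative) the focal behaviour, the remaining
behaviours rescaled proportionally so the day still sums to 1440 min,
with a pointwise 95% delta-method band.

## Package layout

- `R/composition.R` — closure, ilr/pivot coordinates, compositional mean,
  ternary coordinates
- `R/accelerometry.R` — non-wear detection, cut-point classification,
  valid-day/valid-week rules, averaging
- `R/cognition.R` — score reversal, z-scoring, inclusion criteria,
  domain composites
- `R/inference.R` — moderator categorisation, compositional OLS, type II
  F-tests, backward selection, BH-FDR, pivot rotation
- `R/reallocation.R` — one-for-remaining grids and prediction curves
- `R/synthetic.R` — logistic-normal cohort generator and epoch-series
  fixtures
- `R/pipeline.R` — eligibility, demographics, YAML-configured pipeline
- `vignettes/time-use-cognition.Rmd` — the methods vignette
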
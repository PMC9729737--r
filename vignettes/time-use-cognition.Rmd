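---
title: "Methods: compositional analysis of 24-hour time use and cognition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: compositional analysis of 24-hour time use and cognition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codatime)
```

## Why compositions

The 24-hour day is an exhaustive partition into sleep, sedentary
behaviour (SB), light physical activity (LPA) and moderate-to-vigorous
physical activity (MVPA). The four durations sum to 1440 minutes for
everyone, so any one of them is a deterministic function of the other
three: entering all four into a regression gives a perfectly collinear
design, and entering a subset silently conditions on the omitted
behaviours. Compositional data analysis resolves this by working with
log-ratios. `codatime` uses *pivot coordinates*: for the ordered parts
$(x_1, x_2, x_3, x_4)$,

$$z_k = \sqrt{\tfrac{4-k}{4-k+1}}\,
  \ln\!\frac{x_k}{\left(\prod_{j>k} x_j\right)^{1/(4-k)}},\qquad k = 1,2,3.$$

Under the default order (sleep, SB, LPA, MVPA), $z_1$ is sleep against
the geometric mean of the waking behaviours, $z_2$ is SB against the two
activity intensities, and $z_3$ is the LPA:MVPA balance. The transform is
scale invariant (closure does not change it), a bijection onto
$\mathbb{R}^3$, and an isometry between Aitchison distance on the simplex
and Euclidean distance on the coordinates — all three properties are
asserted by the test suite against independent brute-force computations.
The normalising constants $\sqrt{(D-k)/(D-k+1)}$ are the standard
orthonormal pivot-coordinate choice; the construction is defined verbally
in the literature this package follows, and the orthonormal constants are
the assumption that makes the coordinates an isometry.

The *compositional mean* is the part-wise geometric mean closed back to
1440 min; it coincides with the inverse ilr of the arithmetic mean of the
ilr coordinates, and the equivalence of the two definitions is itself a
test.

No zero-replacement is performed anywhere. A behaviour with zero average
minutes has no log-ratio image; rather than impute, `closure()` and
`ilr_transform()` reject non-positive parts, and a participant whose
valid-day average contains a zero behaviour is excluded with a typed
reason. Device-derived daily averages of exactly zero minutes in a
behaviour are, in this population, better read as processing errors than
as data.

## Accelerometry rules

Inputs are 1-minute epoch activity values in g-min with diary sleep
intervals. The processing chain applies, in order:

* **non-wear**: maximal runs of $\ge 60$ consecutive epochs at
  $\le 25$ g-min;
* **classification** with precedence sleep $>$ non-wear $>$ intensity;
  waking worn epochs are MVPA above 93 g-min, LPA in $(48, 93]$, SB at or
  below 48. The published bands ("$<48$", "$>48$", "$>93$") leave the
  exact values 48 and 93 unassigned; we close both gaps downward (48 is
  SB, 93 is LPA) so that the bands are disjoint and SB remains the
  default waking state;
* **valid day**: waking wear time $1440 - \text{sleep} - \text{non-wear}
  \ge 600$ min ("at least 10 waking hours" read as an inclusive bound);
* **valid week**: $\ge 3$ valid weekdays and $\ge 1$ valid weekend day,
  with day type taken from the input rather than parsed from dates
  (synthetic fixtures carry no calendar);
* **averaging**: arithmetic means over valid days only, then the four
  behaviour means are closed to 1440 min, which redistributes average
  non-wear proportionally. Closure happens after averaging, not per day,
  matching the convention of averaging each activity across the recording
  period before forming the composition.

Diary sleep is trusted over the accelerometer signal: a 120 g-min epoch
inside a diary sleep interval is sleep. Whether the original non-wear
rule operated on epoch means or sub-epoch counts is not decidable from
published descriptions; the epoch-value reading is this package's
contract.

## The regression engine

For each cognitive outcome the initial model contains covariates (age,
sex, site, education, smoking), moderator main effects (TV tertile,
recreational-PA category, sleep quality), the 3-df composition block, and
the three composition × moderator interaction blocks. Reference levels:
male, Adelaide, never-smoker, low TV tertile, `over30` recreational PA,
good sleep. TV tertiles are empirical-quantile splits (interpolating type-7
quantiles, ties at a cut going to the lower category); recreational PA is
none / `(0, 30]` / over 30 min, with exactly 30 min in the middle
category; the PSQI quality item dichotomises as good (0–1) vs bad (2–3).

**Type II F-tests.** Each term group $g$ is tested by
$F = \frac{(\mathrm{RSS}_{-g} - \mathrm{RSS}_{-g+g})/\mathrm{df}_g}
{\mathrm{MSE}_{\text{full}}}$, where the reduced model omits $g$ *and
every term containing* $g$ (marginality), and the denominator uses the
full model's residual mean square and degrees of freedom. Composition and
interaction blocks are multi-df joint tests. The implementation works on
explicit design matrices via QR factorisations; the test suite requires
agreement to 1e-8 relative with a brute-force oracle that refits every
nested model through R's formula machinery, and with `car::Anova` on a
factor-only fixture.

**Backward selection** removes the interaction block with the largest
type II p-value while that p is $\ge 0.05$ (ties broken in the fixed
order TV, recreational PA, sleep quality, for determinism); the
composition block is then tested and may be removed only when no
interaction block remains; finally the remaining covariates and free
moderator main effects are tested with one collective F-test. Two
readings of the final step are defensible; the default *retains* the
covariate block regardless of its p-value (final models in this
literature report non-significant covariates), and
`drop_covariates = TRUE` gives strict removal. When an interaction block
survives, its moderator's main effect is excluded from the collective
test — removing it would violate marginality.

**FDR family.** Benjamini–Hochberg adjustment is applied across the term
p-values *within one outcome's final model* (seven to nine terms). This
family choice reproduces published within-model adjusted p-values from
their raw counterparts in the test suite. Note that the step-up
adjustment is monotone and never below the raw p, but it is *not*
idempotent — re-adjusting adjusted values inflates them further — so
adjusted p-values are never fed back into the procedure.

**Pivot coefficients.** Per-behaviour summaries refit the final model
under the four rotations of the partition and report each first
coordinate: the behaviour against the geometric mean of the remaining
three. The rotated bases span the same column space, so fitted values are
identical across refits (asserted to 1e-9), and the four pivot
coefficients always sum to zero.

**Missingness** is handled by listwise deletion per outcome, so each
outcome model has its own complete-case $n$, which is reported.

## Reallocation curves

`one_for_remaining_grid()` moves the focal behaviour by $\delta$ (15-min
steps by default, $\pm 60$ min) and rescales the remaining parts by
$(1440 - x_f - \delta)/(1440 - x_f)$, conserving the day exactly. Grid
rows that would push a part to or beyond the simplex boundary are
truncated, not errors. Curves are predicted at a fixed profile — by
default the sample compositional mean, numeric covariates at their means
and factors at reference levels, since published use of these plots was
conditional on significant interactions — with a pointwise delta-method
confidence band from the coefficient covariance (the band construction is
unstated in the source literature; the delta-method band is this
package's documented choice).

## The synthetic cohort

The generator is the package's stand-in for participant-level data, which
is not publicly deposited; everything it produces is labelled synthetic.

* **Compositions** are logistic normal: multivariate normal on the ilr
  scale centred at the ilr of the target mean composition
  (sleep 503, SB 668, LPA 178, MVPA 89 min/day, closed), mapped back and
  closed to 1440. This is the distribution under which the downstream
  ilr regression is correctly specified — the natural choice when the
  source reports no generative model. The default ilr covariance
  `diag(0.041, 0.072, 0.179)` is derived by the delta method from
  minute-scale coefficients of variation typical of this population
  (sleep ±57, SB ±90, LPA ±50, MVPA ±47 min/day): log-part variances
  $\approx$ CV² propagated through the pivot contrasts. It is a package
  default, not an estimate of any cohort's covariance.
* **Covariates**: age truncated normal on the 60–70 eligibility window
  (65.5 ± 3.0; truncation by inverse-CDF keeps draws deterministic),
  68% female, two sites (207/384 Adelaide), education 16.5 ± 3.2 years,
  smoking 37/2/61% current/previous/never, PSQI quality item at
  27/54/17/2% for ratings 0–3, gamma TV minutes (mean 130, SD 80), and
  recreational PA as a three-part mixture (54% none, 19% up to 30 min,
  27% over 30 min) with within-category minute distributions.
* **Outcomes** are linear in the ilr coordinates, covariate indicators
  and optional composition × moderator products, plus Gaussian noise.
  The default processing-speed model encodes behaviour-vs-remaining
  pivot coefficients (sleep 0.28, SB −0.33, LPA −0.16, MVPA 0.20) via
  $\beta^{\text{pivot}}_j = \sqrt{4/3}\,c_j$ with $c$ the clr
  coefficient vector; the other outcomes carry covariate effects only
  (site, age, sex, education, recreational PA at their reported
  magnitudes) and null composition and interaction effects, mirroring
  the cross-sectional pattern the generator emulates.
* **Eligibility injection** uses exact disjoint counts (default 21
  invalid-accelerometry, 21 missing-covariate of 426) rather than
  fractions, so the accounting 426 → 384 is reproduced deterministically
  at the default conditions.
* **Epoch series** realise per-day minute targets as contiguous blocks
  with values drawn uniformly within each class's cut-point band (MVPA
  capped at 500 g-min — only the band matters downstream). Sleep epochs
  are drawn *above* the non-wear threshold (quiet but worn), so a diary
  sleep block never extends a detectable non-wear run and the chain
  round-trips to the targets exactly. Non-wear targets in $(0, 60)$ min
  are rejected: they cannot be realised as a detectable run.

All randomness in a cohort flows from one seeded stream. An earlier
design seeded each component with nearby integers; Mersenne-Twister
streams from nearby seeds can be measurably correlated (we observed
$r \approx -0.047$ between two components at $n = 5000$, enough to bias a
regression noticeably), so per-component seeding was abandoned.

What the generator does *not* emulate: circadian structure beyond a
single diary sleep block, day-to-day autocorrelation, measurement error
in the cut-point classification, informative missingness, or any
non-linear composition–outcome relationship. Passing tests therefore
certify the pipeline's arithmetic and its statistical calibration under a
correctly specified logistic-normal world, not robustness to the ways
real accelerometry deviates from it.

## Cognitive outcomes

Global cognition is the raw ACE-III total (0–100), used as its own
outcome without standardisation. The four domain composites (long-term
memory, short-term memory, executive function, processing speed) are
unweighted means of component z-scores ("collated" admits several
readings; the unweighted mean is the standard one and is recorded here).
Measures where lower raw scores mean better performance are multiplied by
−1 before z-scoring (sample SD, $n-1$ denominator). A composite is
missing unless every component is present and the participant passed all
accuracy-based inclusion rules affecting it; rules are config-driven with
a strict `< 50%` accuracy threshold as default, because the exact
published rule list lives in unavailable supplementary material.

## Numerical choices and problem sizes

Tolerances asserted in tests: ilr round-trip and isometry at 1e-9,
type II oracle equivalence at 1e-8 relative, grid conservation at 1e-9.
Ties in backward selection and the 48/93 g-min boundary assignments are
fixed as described above. Rank-deficient designs are an error naming the
aliased columns rather than a silent drop; empty factor levels are
dropped at fit time.

Simulation sizes used by the test suite and the acceptance script were
chosen as the smallest that make the Monte-Carlo error negligible
relative to the property under test: 1000 null cohorts of $n = 384$ for
the size of the composition F-test (95% binomial band 0.036–0.064 around
0.05), $n = 5000$ for 3-SE parameter recovery in tests, $n = 20000$ for
the acceptance script's pivot-coefficient recovery, and 10000 draws for
the generator's compositional-mean check (1% per part).

## Known limitations

* Cross-sectional OLS only: no mixed models, survey weights, or multiple
  imputation.
* The published cohort's own F statistics, correlations and coefficient
  estimates are not reproducible without the unreleased participant data;
  the package reproduces the *procedures* and their in-print arithmetic,
  and calibrates the machinery on synthetic data.
* One-for-one reallocations between named behaviour pairs are out of
  scope (one-for-remaining only).
* Raw 100-Hz signal processing, auto-calibration and sleep detection from
  the signal are upstream of this package; it begins at 1-min epochs with
  diary sleep intervals.
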
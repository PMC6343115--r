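---
title: "Observed versus expected psychometric scores: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Observed versus expected psychometric scores: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(excesscohort)
```

## The problem

How much worse (or better) off is an exposed cohort than it "should" be?
When an exposed group — here, adults assessed decades after a disaster,
either survivors or bereaved — is compared with a general-population
reference sample, crude group comparisons confound exposure with age and
gender composition. This package implements the indirect-standardization
answer: every cohort participant is ascribed the *expected* value of each
outcome, namely the mean among reference-sample members of the same gender
and the same exact age in completed years, and the analysis summarizes how
far observed values sit above or below those expectations.

Two instruments are scored:

* **HSCL-10** — ten anxiety/depression symptom items rated 1 (not bothered)
  to 4 (bothered a great deal). The score is the mean of valid items; one
  missing item is tolerated (at least 9 of 10 required). A mean score of
  **1.85 or above (inclusive)** flags a clinically significant symptom
  level ("caseness").
* **Crisis Support Scale (4 items)** — perceived social support rated 1
  (never) to 5 (very often/always); mean of valid items, at least 3 of 4
  required; no agreed cut-off, so no caseness for this outcome.

Internal consistency is summarized by Cronbach's alpha on listwise-complete
rows with unbiased (n−1) variances. The instruments' handling of
missingness is deliberately asymmetric to the analysis's: a participant who
cannot be scored on one outcome still contributes to the other.

## Estimands

For each outcome, overall and within each gender and each exposure group:

* mean difference \(\bar{y}_{obs} - \bar{y}_{exp}\);
* **ratio of means** \(\bar{y}_{obs} / \bar{y}_{exp}\) — reported as the
  headline `mean_ratio`. The phrase "mean ratio" is ambiguous between this
  and the mean of per-participant ratios; the ratio of means is what the
  printed aggregate values are consistent with, so it is the headline
  quantity, while the mean of per-participant ratios is retained alongside
  it (`mean_ratio_participant`) because the per-participant ratios are also
  what the dot-plots display;
* standardized effect size: the mean difference divided by the sample
  standard deviation (n−1) of the *observed* scores in the subgroup being
  summarized. Subgroup effect sizes use the subgroup's own SD — the
  alternative (the total-sample SD) is defensible, but subgroup-specific
  standardization keeps the estimand self-contained and is documented here
  as the package's choice;
* excess caseness (distress only): observed proportion at or above the
  cut-off minus the mean of the participants' expected caseness
  probabilities (each the proportion of cases in the participant's
  reference cell).

## The doubly-stratified bootstrap

Percentile confidence intervals come from resampling **both** samples:
reference rows with replacement within each gender, cohort rows with
replacement within each gender × group cell, each stratum keeping its
original size. Crucially, the age-by-gender expectation table is **rebuilt
inside every resample** and expected values re-ascribed, so the intervals
carry reference-sample uncertainty, not only cohort uncertainty.

```{r boot-demo, eval = FALSE}
cfg <- synthetic_config(seed = 1)
ref <- score_responses(score_responses(generate_reference(cfg), hscl10()), css4())
coh <- score_responses(score_responses(generate_cohort(cfg), hscl10()), css4())
ci <- run_bootstrap(coh, ref, config = bootstrap_config(n_resamples = 1000, seed = 2))
```

Numerical choices, all fixed and tested:

* **Quantile rule.** Interval bounds are empirical quantiles at
  \(\alpha/2\) and \(1-\alpha/2\) with linear CDF interpolation
  (`stats::quantile` type 7). At \(B = 10\,000\) the choice of rule moves
  bounds by \(O(1/B)\); at the small \(B\) used in unit tests it is
  test-relevant, which is why the rule is pinned.
* **Empty cells in resamples.** Resampling the reference within gender can
  empty an age cell even when the full table covers it. The fallback
  searches ages at distance 1, 2, … years within the same gender and pools
  *all* rows found at the first non-empty distance (both sides, n-weighted
  — equivalent to pooling the underlying persons). The horizon is 5 years;
  beyond it the participant is unmatchable, the affected estimand is
  dropped for that replicate only, and the shortfall is reported per
  estimand (`n_effective_resamples`), with a warning when more than 1% of
  replicates are lost. Age matching is otherwise on exact integer age —
  never on bands.
* **Random numbers.** One parent seed draws one child seed per replicate;
  each replicate then seeds its own stream. The replicate set is therefore
  independent of execution order, and two runs with the same seed and
  configuration produce byte-identical result tables.
* **Point estimates.** Always computed from the original samples, never as
  replicate means. A percentile interval need not contain the point
  estimate in pathological cases; this is logged as a warning rather than
  "corrected".

## The synthetic data generator

No raw interview data are available, so the package carries a generator
that emulates both tables. Each person has one standard-normal latent trait
per scale; item \(j\) has latent value
\(\lambda t + \sqrt{1-\lambda^2}\,\varepsilon_j\), cut by fixed thresholds
into the ordinal range. This is the simplest mechanism that gives
independently tunable internal consistency (via \(\lambda\)), mean shifts
(via the trait mean) and skew (via thresholds).

Default conditions (chosen once, by calibration against the reference
descriptive statistics the analysis assumes, and not revisited):

| quantity | value | rationale |
|---|---|---|
| reference / cohort size | 3694 / 165 | study sizes |
| age ranges | 18–74 / 27–74 | reference coverage contains the cohort |
| gender / group balance | 51.5% female / 52.7% survivors | cohort composition |
| HSCL-10 loading | 0.78 | reference alpha ≈ 0.89 after ordinal attenuation |
| HSCL-10 thresholds | `qnorm(1 - c(.24, .05, .02))` | mean ≈ 1.31, caseness ≈ 0.11, right skew |
| CSS loading | 0.675 | reference alpha ≈ 0.70 |
| CSS thresholds | `qnorm(1 - c(.97, .92, .80, .60))` | mean ≈ 4.29, left skew |
| latent shifts | +0.3818 distress (cohort), +0.3728 extra (bereaved), −0.8027 support | subgroup means ≈ 1.47 / 1.67 and 3.72 |
| missingness | 0.005 per item, MCAR | a handful of missing items per 165 × 14 responses, matching the scale of item non-response in face-to-face interviews; MCAR keeps the scoring rules the only systematic mechanism |

Ages are uniform on their range by default (no age distribution is
specified for either sample; a weight vector can be supplied). With ~32
reference persons per (gender, age) cell the generator effectively
guarantees full cell coverage, so on the full reference every ascription is
exact (`fallback_distance` 0).

`score_moments()` computes the population mean, SD and caseness probability
of a scale score under any latent shift by one-dimensional quadrature over
the trait (items are conditionally independent given the trait; the
conditional distribution of the item sum is an exact discrete convolution).
`latent_shift_for_effect()` inverts this map, which is how
parameter-recovery tests inject shifts with a *known* standardized effect
on the observed score scale.

What the generator deliberately does **not** model: covariance between the
two outcomes, age or gender trends in the outcomes, informative
non-response, or any covariate structure (education, finances) beyond age
and gender. Passing tests on synthetic data therefore demonstrate that the
estimators recover the generator's truth under the stated conditions — not
that real interview data satisfy those conditions.

## Degenerate inputs and tie-breaks

* Out-of-range or non-integer item responses fail with the offending item
  index; wrong item counts fail outright.
* An all-equal replicate distribution yields a degenerate interval
  (low = high), which is legal.
* Alpha is undefined (and errors) for zero total-score variance, fewer than
  2 items, or fewer than 3 complete rows.
* An empty eligible cohort is legal (warned, logged); an empty stratum
  table is an error.
* Caseness uses `>=` — a score exactly at 1.85 is a case.
* Reporting rounds half-up at the printed precision (`report_round`,
  `report_percent`); all internal computation is full precision.

## Problem sizes used by the test-suite

The suite checks coverage of the null configuration with 200 simulation
replicates at \(B = 500\), parameter recovery over effects
\(\{0, 0.4, -0.7\}\) with 50 replicates at cohort 500 / reference 4000,
bootstrap correctness against exhaustive enumeration of all 108 joint
resamples of a 5-person instance at \(B = 20\,000\), and byte-identical
reproduction of a full-scale run at \(B = 10\,000\). These sizes keep each
property estimable within tight Monte-Carlo tolerance while the whole suite
stays comfortably interactive.

## Known limitations

* Exact-age matching requires a dense reference; with sparse references the
  fallback pooling (not part of the original estimand) engages more often
  and is then a modelling choice, visible via `fallback_distance`.
* Percentile intervals are first-order accurate only; no BCa, studentized
  or jackknife variants are provided.
* The caseness analysis is only as meaningful as the cut-off; 1.85 is a
  screening convention, not a diagnosis.
* Expected caseness for a participant is the reference cell's observed
  proportion; in tiny cells it is noisy, which the bootstrap propagates but
  does not remove.
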
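---
title: "Ceiling lines, the necessity effect size, and its permutation test"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ceiling lines, the necessity effect size, and its permutation test}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(necessity)
```

## The model

Necessary condition analysis treats a predictor X as a *constraint* on an
outcome Y rather than as an average driver of it. If high Y values never
co-occur with low X values, the X–Y scatterplot has an empty upper-left
corner; the analysis quantifies that emptiness. All quantities are defined
relative to a **scope** rectangle S = [x_min, x_max] × [y_min, y_max],
empirical by default (the observed minima and maxima). A **ceiling line**
bounds the cloud from above; the area C between the ceiling and the scope's
top, divided by the scope area, is the effect size

d = C / S.

d is a fraction of the feasible space that the condition renders
unreachable, which makes it translatable into practice through two derived
quantities: the **outcome inefficiency** (the ceiling height at the scope's
left edge, as a share of the outcome range: the outcome levels no condition
level can constrain) and the **condition inefficiency** (the share of the
condition range to the right of the point where the ceiling reaches the
outcome maximum: condition levels not needed even for the best outcome).
**Bottleneck tables** invert the ceiling: for each outcome level (as a
percentage of the outcome range — 0% = y_min, 100% = y_max, keeping the
table consistent with the scope-relative definition of d) they give the
minimum condition value required.

### Assumptions

* Necessity is directional and fixed here to the upper-left-corner case
  (high Y requires high X). Other corners would need reflected data.
* The scope determines everything. Empirical scopes make d sensitive to
  extreme observations — the motivation for the outlier screen below — and
  two unrelated variables can produce an empty corner by accident, which is
  what the permutation test guards against.
* Observations are exchangeable under the null of "no necessity
  relation"; the permutation test relies on this, not on any distributional
  form.

## Estimators

**CE-FDH.** The free-disposal-hull step ceiling
c(x) = max{ y_i : x_i ≤ x }, right-continuous and non-decreasing. It passes
through the *peers*: observations not dominated by any other point with
smaller-or-equal x and greater-or-equal y. Every observation lies on or
below the step, so its accuracy is 100% by definition. The zone area is the
exact sum over steps, not a numerical integral.

**CR-FDH.** An OLS line through the upper-left corner vertices of the
CE-FDH step — one vertex per peer, at the peer's own (x, y). The published
description of this estimator ("a regression line joining the dots of the
step ceiling") leaves open whether the dots are the corner vertices or,
say, edge midpoints; we regress through the corner vertices because the
peers are the observations that actually bind the ceiling, and the choice
is isolated in one function so it could be swapped. With fewer than two
distinct corners (the upper-left corner of the scope is occupied) the line
is undefined and the fit errors, pointing the user to CE-FDH. Since the
line can leave the scope rectangle, it is clipped to [y_min, y_max] before
any area, inefficiency or bottleneck computation, which keeps d in [0, 1].

Accuracy for CR-FDH is the percentage of observations on or below the
line; "on" is decided with an absolute tolerance of 1e-9 × (outcome range),
so exact-contact points count as below. Fits under 95% accuracy are flagged
`interpretable = FALSE` and the analysis pipeline marks the step ceiling as
the line to read instead.

### Tie-breaks and degenerate inputs

* Ties in x among potential peers: only the highest y survives. Ties in y
  across different x: the leftmost point is the peer.
* The step is right-continuous; a peer lies on its own jump.
* A scope wider than the data on the left gets ceiling value y_min on the
  uncovered stretch (no constraint evidence there), so the first breakpoint
  is always at x_min.
* Zero-width scopes, observations outside the scope, and constant columns
  raise errors rather than producing NaN effect sizes; in the pipeline
  these errors are caught per condition so one bad column does not abort
  the others.

## The permutation test

The null model re-pairs the observed y values with the observed x values
uniformly at random (a permutation of y, holding x fixed). Both marginals
are preserved, so the empirical scope is unchanged and is held fixed across
replicates — this is exact, not an approximation. For each of N replicates
(default N = 10,000) the same ceiling technique is refitted and d*
recorded;

p = #{ d* ≥ d_observed } / N.

This follows the estimator's published form, with no +1 continuity
correction; `plus_one = TRUE` switches to (count + 1)/(N + 1) for users
worried about p = 0 artifacts. A permutation that happens to occupy the
upper-left corner leaves fewer than two corner points for CR-FDH; such
replicates contribute d* = 0, consistent with their flat, zone-free
ceiling. Replicates reuse the fixed x ordering, so a test at N = 10,000 and
n in the hundreds runs in seconds. Given a seed, results are reproducible
bit for bit.

Significance is read strictly: p < alpha (default 0.05). The test is
approximate in the usual sense for necessity effect sizes — the observed
statistic is not included in the null set — giving a type-I error of about
N_reject/(N+1) ≈ alpha on continuous data, which the test suite verifies
empirically (1000 independent-uniform datasets of n = 100, 200 permutations
each, rejection rate checked against the exact binomial 99% interval around
0.05; these sizes keep the whole suite under a minute while leaving the
binomial check sharp enough to catch a mis-calibrated test).

## Preprocessing

Applied in this order by `preprocess_nca()` / `run_nca()`, before any group
split so that imputation means and outlier screens use the full sample:

1. **Mean imputation** of missing analysis-column entries (tokens: empty
   cell, `NA`, `NaN`, case-insensitive). Appropriate for the ~1% missingness
   typical of the surveys this method is applied to; not for heavily
   incomplete data.
2. **Skewness screen**: adjusted Fisher–Pearson (bias-corrected) sample
   skewness per column, flagged when |G1| > 2.0. The threshold is the
   conventional "highly skewed" cut; the estimator is the one common
   statistics software reports by default.
3. **Outlier removal** on selected columns (default: the flagged ones):
   values at least k = 3 standard deviations from the mean are removed as
   whole records. Mean and SD are computed once on the full input — a
   single pass, deliberately not iterated, and the report says so because
   re-invocation can remove more rows. The SD here is the population (1/n)
   form and the boundary is inclusive (exactly 3 SD away is removed), with
   a 1e-12 relative tolerance so that analytically-exact boundary cases are
   not lost to floating-point rounding.

## Interpretation benchmarks

`interpret_d()` maps d to small (< 0.1) / medium (0.1–0.3, inclusive at
both ends, reading "between" inclusively) / large (> 0.3). For the
Pearson-r complement, `interpret_r()` offers the classic Cohen bands
(|r| < 0.10 below-small, 0.10–0.29 small, 0.30–0.49 medium, ≥ 0.50 large)
and an empirical-benchmark scheme that places |r| in quartile bands of the
distribution of published individual-differences correlations (25th/50th/
75th percentiles at 0.11/0.19/0.29). The two schemes often disagree — an
r of 0.18 is "small" for Cohen but sits in the second quartile of effects
actually published in the field — which is exactly the contrast the
complement report is meant to surface.

## Reporting rules in the pipeline

`run_nca()` fits both ceiling techniques per group × condition, attaches
permutation p-values (each test's sub-seed derived deterministically from
the master seed), and:

* flags CR-FDH fits under 95% accuracy and marks CE-FDH as the
  interpretable line for that condition;
* emits bottleneck tables only for conditions significant at alpha in at
  least one technique, tabulating both techniques and leaving the 95% rule
  to say which column to read — the literature does not fix which ceiling
  the bottlenecks of a doubly-significant condition should use, so both are
  given;
* reports bottleneck requirements in the condition's actual units by
  default (matching how practitioners quote them, e.g. hours per week),
  with `percentage_range` units as an option, since published tables mix
  both conventions and the two cannot always be told apart;
* rounds only at the presentation layer (2 decimals for d, r and
  percentages, 3 for p); `report.json` keeps full precision.

## Synthetic data

Three generators make every stage testable without external downloads; all
are pure functions of their parameters and a seed.

* `gen_ceiling_data()`: x uniform on the scope width, y uniform between the
  floor and a known linear ceiling. The fraction of the scope above the
  ceiling is available analytically (`true_ceiling_d()`), giving
  ground-truth recovery targets. At n = 2000 the CE-FDH and CR-FDH
  estimates sit within 0.05 of the truth, and the CR-FDH slope within 0.05
  of the generating slope (checked over 20 seeds).
* `gen_null_data()`: independent uniforms — the permutation test's null.
* `gen_student_like()`: independent truncated-normal columns matching a
  profile of printed summary statistics (mean, SD, min, max per variable),
  with `student_profiles()` providing two realistic cohorts of university
  students (face-to-face, n = 159; online, n = 76) spanning GPA, admission
  grade, weekly study hours and a conscientiousness score. The underlying
  normal parameters are moment-matched (closed-form truncated-normal
  moments, Nelder–Mead) so the *truncated* distribution hits the printed
  mean and SD; naively using the printed values as the untruncated
  parameters misses the mean by ~12% when a bound sits close to it, as it
  does for study hours. Draws use inverse-CDF sampling, so exactly n values
  are produced per seed. These columns are independent: the generator
  emulates marginal summaries, not correlation structure or true ceiling
  relations, so pipeline tests on it validate shapes, grouping and
  reporting — not effect-size recovery, which the ceiling generator covers.

What passing tests on these generators show about real data is accordingly
limited: real datasets have dependent predictors, non-uniform fills under
their ceilings, and measurement error in both axes, none of which the
generators emulate.

## Known limitations

* Necessity inference from observational data is not causal; an empty
  corner can arise from unrelated skewed marginals, and large samples
  inflate the permutation test's sensitivity.
* Only the upper-left necessity direction is implemented.
* No confidence intervals for d, and no multiple-testing correction across
  conditions — p-values are reported per condition as is.
* Mean imputation and single-pass outlier screening are the conventional
  choices for this analysis, not the statistically strongest ones.
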
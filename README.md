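# necessity

Necessary condition analysis (NCA) for bivariate data: ceiling-line
estimation, the necessity effect size *d* with an approximate permutation
test, inefficiencies, bottleneck tables, and benchmark-based interpretation
of Pearson correlations as a complement.

## The question and the method

Classical effect sizes (Pearson's *r*, regression slopes) quantify whether a
predictor is on average *sufficient* to raise an outcome. NCA asks a
different question: is a certain level of the predictor X *necessary* for
the outcome Y to reach a certain level at all? Graphically, necessity shows
up as an empty upper-left corner of the X–Y scatterplot: high outcomes are
never observed at low condition levels.

The method bounds the data from above with a **ceiling line** and measures
the empty **ceiling zone** C it encloses relative to the **empirical
scope** S, the rectangle
`[min x, max x] × [min y, max y]`. The effect size is

```
d = C / S,          0 ≤ d ≤ 1
```

conventionally read as small (*d* < 0.1), medium (0.1 ≤ *d* ≤ 0.3) or
large (*d* > 0.3). Two ceiling estimators are implemented:

* **CE-FDH** (ceiling envelopment – free disposal hull): the
  non-decreasing step function `c(x) = max{ y_i : x_i ≤ x }`, running
  through the non-dominated "peer" observations. Every observation lies on
  or below it (100% accuracy by construction); suited to discrete or
  categorical data.
* **CR-FDH** (ceiling regression – free disposal hull): the OLS straight
  line through the CE-FDH corner points, suited to continuous data. Some
  observations may end up above the line; when fewer than 95% lie on or
  below it, the fit is flagged as not appropriate for interpretation and
  the step ceiling should be read instead.

Around *d* the package computes the ceiling **accuracy**, the **outcome
inefficiency** (share of the outcome range reachable with no condition
requirement), the **condition inefficiency** (share of the condition range
not needed even for the maximum outcome), an approximate **permutation
test** (y re-paired with x at random, 10,000 replicates by default,
`p = #(d* ≥ d) / N`), and **bottleneck tables**: for each outcome level
(percent of its range), the minimum condition level required, with `NN`
("not necessary") and `NA` ("not attainable") sentinels.

## Worked example

Fill the unit square below the true ceiling y = x with 300 points, so the
empty triangle above the diagonal is half the scope (true *d* = 0.5):

```r
library(necessity)

obs <- gen_ceiling_data(n = 300, slope = 1, intercept = 0, seed = 42)
fit <- fit_ce_fdh(obs)
fit
#> CE-FDH (step ceiling), x vs y, n = 300
#>   ceiling zone C = 0.423321, scope S = 0.871405, d = C/S = 0.4858
#>   accuracy = 100.00%

permutation_test(obs, "ce_fdh", n_permutations = 1000, seed = 42)
#> Permutation test (CE-FDH, 1000 permutations, seed 42): d = 0.4858, p = 0.0000

bottleneck_table(bottleneck(fit, levels = seq(0, 100, 25)))
#> Bottleneck table (actual units):
#>  y (%)        x
#>      0       NN
#>     25 0.252458
#>     50 0.453303
#>     75 0.719112
#>    100 0.940015
```

The estimated step ceiling recovers *d* ≈ 0.49 against the true 0.5; no
permuted re-pairing of the 300 points reached an effect size this large, so
p = 0. The bottleneck column reads, e.g.: to reach 75% of the outcome range
the condition must be at least 0.72, while the lowest quarter of the
outcome range needs no condition at all beyond its minimum (`NN`).

The full pipeline — CSV input, preprocessing (mean imputation, skewness
screen, ≥3 SD outlier removal), per-group fits for several conditions,
p-values, bottlenecks for significant conditions and a Pearson-*r*
complement — is one call:

```r
ana <- run_nca("students.csv", outcome = "gpa",
               conditions = c("study_time", "conscientiousness"),
               group = "setting", n_permutations = 10000, seed = 42)
ana                      # printed tables, 2-decimal presentation
write_nca_report(ana, "report/")   # report.json, table2.csv, bottlenecks.csv
```

or, from a shell, via the thin front end in `inst/cli/nca.R`:

```sh
Rscript inst/cli/nca.R run --input students.csv --outcome gpa \
    --conditions study_time,conscientiousness --group setting \
    --permutations 10000 --seed 42 --out report/
Rscript inst/cli/nca.R simulate ceiling --n 500 --slope 1 --seed 1 --out fix.csv
```

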
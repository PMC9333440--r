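# gachart

Chart-based 10-year cardiovascular disease (CVD) risk scores, learned by a
genetic algorithm under monotonicity constraints.

## The problem

Clinicians in settings without laboratory access or computers rely on
*risk charts* (WHO, SCORE, PARS): printed lookup tables where a person's
categorized risk factors — sex, age group, systolic blood pressure, total
cholesterol, waist-to-hip ratio, family history of CVD, diabetes, smoking —
select a colour-coded cell giving the 10-year event risk in one of six
bands (≤1%, 2%, 3–4%, 5–9%, 10–14%, ≥15%). Charts are maximally
interpretable but traditionally derived from statistical models whose
discrimination trails machine-learning methods.

`gachart` closes that gap while keeping the chart: it treats every chart
block (a 4×5 blood-pressure × cholesterol grid per stratum, or 4×1 in the
lab-free 1D representation) as a chromosome of ordinal risk levels and
evolves it directly against the area under the ROC curve (AUROC),

```
AUROC = (concordant pairs + ½ tied pairs) / (n_events × n_non-events),
```

subject to the hard constraint that risk never decreases with higher blood
pressure or cholesterol. The operators are roulette-wheel selection,
exhaustive prefix/suffix splice crossover filtered for validity, ±1
single-gene mutation with a minimal monotone repair, and elitist
replacement. Blocks train in descending order of data coverage for (by
default) two full rounds, followed by a per-cell event-ratio adjustment.
Evaluation is stratified 10-fold cross validation. The interpretability of
a chart is summarized by its cell count: the standard 8-feature 2D chart
has 3,200 cells in 160 blocks; the 4-feature 1D chart has 80.

Because no public cohort ships with the package, a planted-model simulator
(`planted_model()`, `simulate_cohort()`) generates cohorts with a known
monotone risk surface and a ~13% event rate at n = 5,432, enabling
recovery and calibration tests end to end.

## Worked example

```r
library(gachart)

spec   <- spec_cvd_1d()                       # 4-feature lab-free chart
model  <- planted_model(spec)                 # ground-truth risk surface
cohort <- simulate_cohort(model, n = 5432, seed = 42)

fit <- train_chart(cohort, spec, params = ga_params(seed = 42))
fit
#> Trained risk chart: 2 round(s), training AUROC 0.6748 -> 0.6873

cross_validate(cohort, spec, params = ga_params(), k = 10, seed = 42)
#> 10-fold CV AUROC: mean 0.6567 (folds 0.643, 0.630, 0.670, 0.621, 0.685,
#>   0.703, 0.655, 0.645, 0.651, 0.665)

lookup_risk(fit$chart, cohort[1:3, ])
#>   level band
#> 1     4 5-9%
#> 2     1 <=1%
#> 3     1 <=1%

cat(render_chart(fit$chart))
#> # risk chart: levels 1..6 = 1:<=1% 2:2% 3:3-4% 4:5-9% 5:10-14% 6:>=15%
#> == block: F|35-44|low ==
#>      bp | risk
#>    160+ |    4
#> 140-159 |    3
#> 120-139 |    1
#>    <120 |    1
#> ...
```

The training AUROC rises from the empirical initialization (0.6748) to the
evolved chart (0.6873); the cross-validated mean (0.6567) is the honest
performance figure, sitting below training as expected for a directly
optimized criterion. Scored records receive their block's gene level and
the corresponding risk band. Charts serialize to a versioned JSON
(`write_chart_json()` / `read_chart_json()`, byte-exact round trip) and
render as text or HTML.

A command-line interface wraps the same functions
(`inst/cli/gachart simulate|train|cv|predict|render|report`), writing
cohort CSVs, chart JSONs, training manifests and per-fold CV tables.

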
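---
title: "Learning monotone risk charts with a genetic algorithm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Learning monotone risk charts with a genetic algorithm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

A chart-based risk score (in the tradition of the WHO, SCORE and PARS
charts) is a lookup table: a person's categorized risk factors select a
cell, and the cell's colour band is the predicted 10-year cardiovascular
risk. `gachart` represents such a chart as a set of *blocks*, one per
combination of stratifier categories (sex, age group, waist-to-hip ratio,
family history of CVD, diabetes, smoking), each block a small matrix of
ordinal risk levels indexed by systolic blood pressure (4 rows) and, in the
2D representation, total cholesterol (5 columns). The 1D representation
drops cholesterol, trading accuracy for a chart that needs no blood test.

The six levels map one-to-one onto the printed risk bands
(≤1%, 2%, 3–4%, 5–9%, 10–14%, ≥15%). Where a numeric risk is needed the
band midpoints (0.5%, 2%, 3.5%, 7%, 12%, 17.5%) are used; these midpoints
are a reporting convention, not estimates — in particular 17.5% for the
open-ended top band is arbitrary.

The epidemiological prior that higher blood pressure and higher cholesterol
never lower risk is a hard constraint: a block is *valid* only if its
levels are non-decreasing along both axes. Monotonicity is non-strict —
real charts plainly repeat a band across adjacent cells, so ties are
allowed. Internally index 1 is the lowest category on both axes; renderers
flip rows so the highest blood pressure prints first, as charts are
conventionally drawn. This is purely presentational.

## The search

Each block is treated as a chromosome and optimized by a genetic algorithm
whose fitness is the *global* AUROC: a candidate is evaluated by
substituting it into the current working chart and scoring the whole
training cohort. This choice (rather than a block-local AUROC) makes a
block's influence proportional to the data it covers, and is cheap because
chart scores are constant within cells: the AUROC of any candidate reduces
to positive/negative tallies per level, computable in O(number of levels)
from precomputed per-cell counts. An equality test against the record-level
Mann–Whitney computation guards this reduction.

Operators:

* **Selection** — roulette wheel without replacement, weight = raw AUROC.
  Because AUROC hovers around 0.5–0.8, raw weights give mild selection
  pressure; an optional `weight_offset` subtracts 0.5 (floored at 1e-6)
  for sharper pressure, off by default to keep selection literally
  fitness-proportional.
* **Crossover** — both parents are linearized row-major (blood-pressure
  major; the order is recorded in the chart JSON so runs are reproducible),
  and every prefix/suffix splice in both orders is generated — at most
  2(L−1) candidates for L genes. Invalid splices are discarded, duplicates
  removed, and two children are drawn from the surviving pool by roulette
  on their fitness. A pool smaller than two is padded with copies of the
  fitter parent. Child fitness is evaluated in the context of the current
  working chart, consistent with the global fitness definition.
* **Mutation** — one uniformly chosen gene moves ±1 with equal
  probability; moves past level 1 or the top level clamp (no wrap-around).
  Every child is mutated (probability 1.0 by default). If the change breaks
  monotonicity, a sweep repair restores it by propagating the change
  through exactly the cells it forces: a forward max-sweep after an
  increase, a backward min-sweep after a decrease. On a one-gene change to
  a valid block this equals the unique minimal-L1 valid matrix that
  preserves the changed gene — verified exhaustively against brute-force
  enumeration for small blocks.
* **Replacement** — elitist: the best chromosome ever seen survives, the
  rest of the next generation is a seeded random draw from parents and
  children. Elitism plus keeping the incumbent block in every initial
  population guarantees the recorded training-AUROC trace never decreases.

Defaults: population 20, at most 50 generations per block visit, early
stop after 10 generations without improvement. These are desk-scale
choices exposed in `ga_params()`; the operators, not the budget, carry the
method.

## Whole-chart training

Blocks are visited in descending order of the number of training records
they cover (ties broken lexicographically by stratum key, so the order is
deterministic), for at most `max_rounds` rounds (default 2); training stops
early when a full round improves AUROC by less than `tol` (default 0.001,
an order below the typical second-round gain). Blocks covering no records
are skipped but keep their initialized chromosome — a deployable chart must
be complete even where the cohort was empty.

Initialization (`empirical` strategy) maps each cell's observed event
proportion to the nearest band midpoint's level; empty cells inherit the
rounded block-mean level (fully empty blocks the cohort-level proportion).
A pooled-adjacent-violators pass along rows then columns, rounding, and a
final upward sweep make every block valid — rounding after PAVA can
reintroduce a one-step violation, which the sweep removes. Each block's
initial population is the incumbent plus ±1-mutation variants (cycling
one, two and three mutation steps for diversity) up to the population
size. A chart fitted elsewhere — for instance one derived from a Cox
survival model — can be supplied via the `external` strategy instead;
survival modelling itself is deliberately outside this package.

After the rounds, a post-hoc modifier sweeps every cell once: a cell whose
covered records are more than 50% positive moves up one level, any other
covered cell moves down one (ratios of exactly 0.5 move down, by the strict
inequality), clamped to the level range and applied only when the block
stays valid; blocked and empty cells are untouched, so the operation is
safely re-runnable. It runs once, globally, after training — not inside the
GA loop — and can be disabled (`posthoc = FALSE`). In cross validation it
sees training folds only.

Evaluation is stratified 10-fold cross validation: fold sizes differ by at
most one, per-class counts across folds differ by at most one, and the
mean of the per-fold AUROCs is the reported number. Fold assignment and
per-fold training seeds derive from one seed, so a CV run is bit-exact
reproducible. Training AUROC is always optimistically biased relative to
CV for this method — the GA maximizes it directly — which is why the CV
mean is the number to quote.

## The synthetic cohort generator

No public cohort accompanies the package, so testing rests on a planted
ground truth. `planted_model()` assigns every chart cell a true event
probability `plogis(baseline + Σ increments)`, with non-decreasing
log-odds increments along blood pressure, cholesterol and age (enforced;
violating increments are a parameter error), and solves the baseline so
the expected event rate over the feature marginals equals the target
exactly. Defaults emulate a middle-aged-and-older cohort of 5,432 adults
with a 13% ten-year event rate (705/5432), a near-even sex split, and
realistic prevalences (diabetes 9%, current smoking 21%, high
waist-to-hip ratio 45%, family history 17%) with modest per-category
log-odds increments (e.g. 0.35 per blood-pressure category, 0.55 per age
group, 0.65 for diabetes). `simulate_cohort()` draws features
independently from the marginals and outcomes as Bernoulli draws from the
cell probabilities; `bayes_auroc()` scores records by their true
probabilities, the ceiling for any cell-constant scorer and the reference
for recovery experiments.

What the generator does *not* emulate: correlation between risk factors
(age and blood pressure are independent here, unlike any real cohort),
censoring and competing risks, missing data, and measurement error.
Passing recovery tests therefore show that the optimizer finds a planted
monotone surface under clean sampling — not that the chart would attain
any particular accuracy on real cohort data. A `raw_values` flag emits
continuous measurements drawn uniformly within each category's range so
the binning and flag-derivation code paths are exercised end to end.

## Numerical and design choices

* Bin boundaries are left-closed, right-open (120–139 means [120, 140)),
  resolving the overlap of printed chart endpoints; binning is monotone by
  construction.
* Age groups default to 35–44, 45–54, 55–64, 65–74, ≥75 — even decades
  over the usual cohort entry floor of 35 years — and are overridable,
  since published chart families differ in their age cuts.
* Missing cholesterol under a 2D spec is an error, never imputed; lab-free
  scoring is what the 1D representation is for.
* AUROC is computed from midranks; undefined (single-class) labels are an
  error surfaced to the caller rather than a silent 0.5.
* All-zero roulette weights fall back to uniform selection.
* All randomness flows through R's RNG seeded once per run; identical
  seeds and inputs give bit-identical charts, histories and CV folds.

## Problem sizes used in the test suite

The packaged tests run the full pipeline at n = 20,000 (monotone
improvement, 20 seeds) and n = 50,000 (surface recovery, 10 seeds) on the
four-feature 1D chart, null-calibration checks at n = 2,000–20,000, and
the acceptance script trains the eight-feature 2D chart at the default
cohort size of 5,432. These sizes were chosen to make sampling noise small
relative to the effects being asserted while keeping a full run in the
low minutes on a single core.

## Known limitations

The GA is a local stochastic search: different seeds give different charts
of similar fitness, and nothing certifies global optimality. Training
AUROC overstates performance by construction (quote the CV mean). The
post-hoc modifier can compress the lowest bands at low event rates, since
nearly all cells sit below a 50% event ratio. And the interpretability
measure — the total cell count — captures chart size only, not how
readable a particular layout is for its users.
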
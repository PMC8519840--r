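---
title: "Methods: intake arrays, rules of compromise, and their verification by simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: intake arrays, rules of compromise, and their verification by simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nutrigeo)
```

## The problem

In the geometric framework of nutrition, an animal's intake of two nutrients
— here total amino acids (AA) and carbohydrate (C), both in millimoles per
individual — is a point in a plane. An animal confined to one
fixed-composition liquid diet can only move along that diet's *nutrient
rail*: the ray from the origin with direction proportional to the diet's
(AA molarity, sucrose molarity). If the rail misses the animal's *intake
target* `T` (the blend it would choose freely), it must compromise. The
*intake array* — the curve connecting the mean intake points of groups each
confined to one rail — reveals the *rule of compromise* in force:

* **no-interaction**: regulate one nutrient only; the array is horizontal
  (carbohydrate regulated) or vertical (amino acids regulated);
* **equal-distance**: the deficit in one nutrient equals the surplus in the
  other; the array is the slope −1 line through `T`;
* **closest-distance**: feed to the rail point nearest `T` (the orthogonal
  projection); the array bows around `T`.

`nutrigeo` implements the full chain from raw feeder-tube masses to these
diagnostics, for trials modelled on queenless bumble-bee micro-colonies of
five workers fed daily over seven days on seven AA:C molar ratios
(0:1, 1:250, 1:100, 1:75, 1:50, 1:25, 1:10) at a fixed 0.5 mol/L sucrose.
Note that total solute deliberately varies across this panel: sucrose is
constant and the amino-acid portion rises with the ratio.

## Diet arithmetic

Ratios are molar and stored as integer pairs, never pre-divided floats, so
diet identifiers stay exact. The total AA molarity of a diet is
`sucrose_molarity * ratio_aa / ratio_c` (a 1:10 diet at 0.5 M sucrose
carries 0.05 M AA), and a named amino-acid mix splits that total across
individual amino acids. The built-in default is an equimolar blend of the
ten essential amino acids; a pollen-proportioned blend is user
configuration, supplied as a two-column table rescaled to sum to one
(`read_mix_file()`; the shipped `pollen_mix_synthetic.tsv` is a synthetic
format example, not measured pollen composition).

## Consumption accounting

Each cage-day records the pre/post masses of two food tubes and the number
of individuals alive during the preceding 24 h. Daily consumed mass is the
summed tube mass change minus the arithmetic mean of that diet's bee-free
evaporation controls. Division by that day's survivor count and by the
solution density (1.06 g/ml for all diets, exposed as a parameter) gives ml
per individual; ml × mol/L = mmol places the cumulative point on the rail.

Numerical choices:

* **Negative corrected days are retained** (with a warning). The
  evaporation correction is an estimate; flooring negatives at zero would
  bias cumulative intake upward. An optional `floor_negative` switch is
  provided for sensitivity analysis.
* **Per-day survivor scaling**: each day's mass is divided by that day's
  survivor count *before* summing, so a mid-trial death changes only the
  divisor of subsequent days. Days with zero survivors contribute nothing
  (logged); gaps in the day sequence warn but do not abort.

## Array fitting and slope tests

`fit_intake_array()` is ordinary least squares of mean carbohydrate intake
on mean amino-acid intake, one point per diet (the seven per-diet means, not
per-cage replicates; a per-cage variant sits behind `use = "cages"`). The
slope standard error comes from the residual variance on `n − 2` degrees of
freedom, and `slope_test()` refers `(β_a − β_h)/SE` to a t distribution with
those degrees of freedom, two-tailed throughout. With seven diets, `df = 5`.
An exact fit (SE = 0) is reported with an `exact_fit` flag rather than an
error: p is 1 when the slopes agree and 0 otherwise.

## Rule classification

`classify_rule()` operationalises the visual comparison of an observed array
with the rule predictions: for each rule it estimates the target by
minimising the summed squared distance between observed per-diet means and
the rule's rail projections — a 200×200 log-spaced grid spanning 0.25×–4×
the range of positive observed intakes per axis, refined by Nelder–Mead —
then ranks rules by minimised SSE. Ties break deterministically toward
`equal_distance`, then `closest_distance`, then `no_interaction_c`, then
`no_interaction_aa`. Geometry is computed in raw mmol space; the
equal-distance rule is unit-dependent by construction, so an optional
per-axis `scale` is available but off by default. Regulating amino acids on
the sucrose-only rail is undefined; that rail is excluded from the
`no_interaction_aa` SSE with a note.

**Identifiability.** The equal-distance projection depends on the target
only through `T_aa + T_c`, and each no-interaction projection only through
the regulated coordinate. For those rules the estimated target is one point
on a ridge of equivalent optima and only the identified combination is
meaningful; the closest-distance rule identifies both coordinates. Parameter-
recovery claims in the tests are therefore stated on the identifiable
quantities.

## Array shape as a function-valued trait

Because intake arrays are often curved, `array_shape()` characterises an
array the way behavioural ecology characterises preference functions. A
cubic smoothing spline (smoothing chosen by generalised cross-validation
unless overridden; a near-zero `lambda` gives the interpolating limit) fits
carbohydrate intake against diet AA molarity, and four summaries follow:
**peak** (x of maximal response, found by a 1000-point grid scan plus local
optimisation; boundary maxima are allowed and flagged, and a flat function
resolves to the leftmost x), **height** (the response at the peak),
**tolerance** (the width of the connected super-level component containing
the peak at elevation `height × (1 − drop_fraction)`, crossings located by
root finding; default `drop_fraction = 1/3`, truncation at a domain end is
flagged), and **strength** (one minus the trapezoid-mean response over the
domain divided by the height; scale-invariant in y). These operational
definitions are fixed here because no canonical closed form exists for them;
`drop_fraction` and the smoothing level are configuration so users can
calibrate against other preference-function software. By default x is the
diet's AA molarity (mol/L); `axis = "aa_intake"` supports the alternative
convention of consumed amino acid (mmol) on the x axis.

## The synthetic-trial generator

`simulate_trial()` is a forward model of the whole measurement process, and
the package's verification device. For each cage, the chosen rule projects
the intake target onto the diet rail; that projection *is* the cumulative
per-individual intake. Daily intake is cumulative/`n_days` — a constant
feeding rate, the simplest defensible assumption in the absence of
within-week feeding dynamics. Each day's true tube mass change is
`volume × density × survivors + evaporation draw`, split 50:50 across two
tubes with independent Gaussian weighing noise per tube (only the summed
change matters downstream). Evaporation is Gaussian per diet per day,
truncated at zero, and the controls are independent draws from the same
model, seven per diet. Deaths are binomial per individual per day after
feeding; a dead individual stops feeding the following day, and `n_alive`
records individuals alive during the preceding 24 h, matching the
consumption convention.

Defaults are the reference trial conditions: 5 individuals, 7 days, the
seven ratios at 0.5 M sucrose, density 1.06 g/ml, and — where no measured
value is available — an evaporation mean of 0.05 g/day (sd 0.01 g), a daily
death probability of 0.01 (survival in such trials is high), weighing noise
of 0.02 g per tube, and an intake target of (0.08 mmol AA, 3.0 mmol C) per
individual per trial: an AA:C blend of roughly 1:37, inside the panel's
1:25–1:50 band, with cumulative carbohydrate near typical observed array
heights (~2.5–3 mmol). These defaults are the simulated study conditions,
chosen once.

With zero noise, zero evaporation spread and zero deaths the pipeline
inverts the simulation at machine precision, and the diagnostic slopes are
exact: equal-distance arrays fit slope −1 (the projections satisfy
`p_aa + p_c = T_aa + T_c`), carbohydrate-only arrays fit slope 0. These
exact identities are what the acceptance checks recompute.

What the generator does *not* emulate: within-day and within-week feeding
dynamics, water-tube consumption, between-colony heterogeneity, behavioural
interactions in micro-colonies, and any feedback of diet on mortality
(deaths are diet-independent). Passing recovery tests therefore demonstrate
that the *pipeline arithmetic and geometry* are correct, not that real bees
follow any particular rule.

## Problem sizes

The shipped tests run the full chain at the design scale (7 diets × 5
individuals × 7 days), with 1–30 cages per diet depending on the check;
the end-to-end recovery study uses 50 seeded replicates at 30 cages per
diet with 0.02 g weighing noise, and the noise-sensitivity study 25 seeds
at each of three noise levels with 3 cages per diet. These sizes give
stable Monte-Carlo margins (3–4 SE) for every stochastic assertion.

## Known limitations

* SSE ranking across rules compares sums over slightly different rail sets
  when a rule is undefined on a rail (documented, logged), which mildly
  favours rules with fewer valid rails near degenerate configurations.
* The equal-distance rule's unit dependence means conclusions can change
  under axis rescaling; the optional `scale` argument makes this explicit
  rather than hiding it.
* Shape summaries depend on the smoothing level; GCV with seven support
  points is serviceable but not precise, which is why the smoothing
  parameter is exposed.

## A worked run

```{r example, eval = FALSE}
cfg <- sim_config(rule = "closest_distance", n_cages_per_diet = 15, seed = 42)
sim <- simulate_trial(cfg)
report <- recovery_report(sim)
report
shape <- array_shape(report$means, sim$panel)
shape
```
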
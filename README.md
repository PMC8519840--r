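# nutrigeo

Geometric-framework analysis of two-nutrient feeding trials: how do caged
animals regulate their intake of amino acids (AA) and carbohydrate (C) when
each group is confined to a single, nutritionally imbalanced liquid diet?

The package is written for nutritional ecologists running (or re-analysing)
cage feeding trials of the classic design — micro-colonies of bumble bees
fed daily on a panel of AA:C molar ratios at fixed sucrose molarity — but
the machinery is general to any two-nutrient rail design.

## The science in brief

An intake of the two nutrients is a point in the (AA, C) plane, in mmol per
individual. A group confined to one diet can only move along that diet's
*nutrient rail*, the ray from the origin with direction proportional to the
diet's (AA molarity, sucrose molarity). Connecting the mean intake points of
groups on different rails gives the *intake array*, whose shape diagnoses
the *rule of compromise* used when the rail misses the animals' intake
target `T`:

* **no-interaction** — regulate one nutrient only: `s = T_reg / u_reg`;
  horizontal (C regulated) or vertical (AA regulated) array;
* **equal-distance** — deficit balances surplus:
  `s = (T_aa + T_c) / (u_aa + u_c)`; array slope exactly −1;
* **closest-distance** — orthogonal projection `s = (T·u)/(u·u)`; the array
  bows around the target.

The fitted array slope `β_a` is tested against hypothetical slopes `β_h` of
−1 and 0 with `t = (β_a − β_h)/SE(β_a)` on `n − 2` df. Curved arrays are
further characterised as a function-valued trait: **peak**, **height**,
**tolerance** and **strength** of smoothed carbohydrate intake as a
function of diet AA molarity.

The pipeline: `build_diet_panel()` → `compute_intake()` (evaporation-
corrected, per-individual consumption accounting from raw tube masses) →
`fit_intake_array()` / `slope_test()` → `classify_rule()` →
`array_shape()`. `simulate_trial()` generates complete synthetic trials
(tube masses, controls, deaths) from agents feeding under a known rule, so
every stage is verifiable by parameter recovery (`recovery_report()`).

## Worked example

Simulate a trial of 15 cages of 5 bees per diet over 7 days on the seven
standard ratios (0:1 … 1:10 at 0.5 M sucrose), with agents feeding by the
closest-distance rule toward a target of (0.08 mmol AA, 3 mmol C), then run
the full analysis:

```r
library(nutrigeo)
cfg <- sim_config(rule = "closest_distance", n_cages_per_diet = 15, seed = 42)
sim <- simulate_trial(cfg)
report <- recovery_report(sim)
report
#> Intake array (7 diets)
#>   slope: -0.03898 (SE 0.02558), intercept: 3.001 mmol
#>
#> Slope tests:
#>  beta_h    slope      se t_stat df p_two_tailed exact_fit
#>      -1 -0.03898 0.02558 37.570  5    2.516e-07     FALSE
#>       0 -0.03898 0.02558 -1.524  5    1.880e-01     FALSE
#>
#> True rule: closest_distance; recovered: closest_distance (target error 0.0365)
```

Reading this: the fitted array is nearly flat (slope −0.039), decisively
unlike the equal-distance diagnostic of −1 (t = 37.6, p < 1e-6) and
consistent with strong carbohydrate regulation (t vs 0 = −1.52, p = 0.19) —
exactly what a carbohydrate-dominated closest-distance feeder on these
carb-heavy rails should produce. Classification nevertheless separates the
rules by SSE and recovers `closest_distance` with the target estimated to
within 4%.

```r
array_shape(report$means, sim$panel)
#> Intake-array shape summary
#>   peak:      0.01335 mol/L
#>   height:    3.005 mmol C
#>   tolerance: 0.05 mol/L at drop 0.333 (truncated at domain end)
#>   strength:  0.002436
```

Carbohydrate intake peaks at an intermediate diet AA molarity (~0.013
mol/L), with a nearly flat profile (strength ≈ 0.002) whose
two-thirds-elevation width spans the whole panel (hence the truncation
flag).

See `vignettes/nutrient-geometry.Rmd` for the model assumptions, parameter
choices, numerical details and limitations.

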
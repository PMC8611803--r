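# mibet — multiple imputation for bounded event times in competing risks

After an umbilical cord-blood transplant, the onset day of acute
graft-versus-host disease (aGvHD) is sometimes absent from registry
records even though the diagnosis itself was made. The time is then not
*unknown* but *bounded*: it lies in an interval such as (0, 100] days
post-transplant. Estimating the cumulative incidence of aGvHD — in the
presence of the competing events graft failure and death, and of
administrative censoring at one year — from such data requires either
discarding the incomplete records or filling the bounded times in.
`mibet` provides the complete toolkit for studying that choice by
simulation: who should use it is anyone comparing missing-data strategies
for interval-censored event times in a competing-risks setting.

## What is inside

* **Data generator** (`sim_config()`, `generate_dataset()`, `apply_mdm()`)
  — a three-cause registry emulation. Cause j ∈ {1, 2, 3} is drawn with
  probabilities (0.65, 0.25, 0.10); the event day is the inverse-transform
  sample `t = ⌈exp(μ_j + σ_j Φ⁻¹(u))⌉` from per-cause log-normal
  distributions LN(log 26, log 2), LN(log 43, log 2), LN(log 77, log 4),
  censored administratively at day 365, plus a binary auxiliary covariate
  (double vs single cord-blood unit, Bernoulli(0.45)). Missingness
  mechanisms: MCAR (any record), MAR (aGvHD records, probability =
  fraction), MNAR (the smallest — or largest — aGvHD times,
  deterministically).
* **Estimators** (`cuminc_aj()`, `cif_at()`, `median()`,
  `median_estimate()`) — the Aalen-Johansen estimator
  `F̂_k(t) = Σ_{t_j ≤ t} Ŝ(t_{j−1}) d_kj / n_j` with the Greenwood-style
  (Marubini–Valsecchi) pointwise variance, and the median time
  `t̂₅₀ = min{t : F̂(t) ≥ 0.5}` with the delta-method standard error
  `SE(t̂₅₀) = SE(F̂(t̂₅₀)) / f̂(t̂₅₀)`, where the density is a local
  gradient of F̂ across the anchors `F̂ ≥ 0.5 + ε` and `F̂ ≤ 0.5 − ε`
  (ε = 0.01).
* **Imputation engines** (`impute_times()`, `imp_spec()`) — five methods
  for the bounded times: unrestricted normal (NORM), log-normal with
  back-transformation (LOGNORM), normal with rejection sampling against
  the record's interval (RESNORM, redraw cap 200 or 500), type 0/1/2
  predictive mean matching (PMM, donor pool 5), and iterative sampling
  from the estimated cumulative incidence conditional on the interval
  (MICI).
* **Pooling** (`pool_rubin()`) — Rubin's rules,
  `T = W̄ + (1 + 1/m) B`.
* **Harness** (`study_design()`, `run_study()`) — the factorial Monte-Carlo
  study (1000 replicates × n = 500 by default) reporting, per method ×
  mechanism × missing fraction × estimand, the mean estimate, the
  empirical SD, the standardized bias `(mean − truth)/SD` and the average
  model-based SE `√(Σ SE²/K)`.

A thin command-line wrapper with `simulate`, `estimate`, `impute` and
`study` subcommands is in `inst/cli/mibet.R`.

## Worked example

```r
library(mibet)
set.seed(2024)
cfg <- sim_config()                     # the default registry emulation
d   <- generate_dataset(cfg)

fit <- cuminc_aj(d, cause = 1)          # complete-data reference
cif_at(fit, 100)
#>       est        se
#> 0.6000000 0.0219089
median_estimate(fit)
#> Median event time: 46 days (SE 4.472, local density 0.00500/day, anchors [43, 49], epsilon 0.01)

dm <- apply_mdm(d, mdm_spec("MAR", 0.5))   # half the aGvHD times -> (0, 100]
cif_at(cuminc_aj(complete_case_filter(dm), 1), 100)
#>        est         se
#> 0.43515850 0.02661474

set.seed(1)
mids <- impute_times(dm, imp_spec("pmm", m = 5))
per <- sapply(1:5, function(k) cif_at(cuminc_aj(complete(mids, k), 1), 100))
pool_rubin(per["est", ], per["se", ])
#> Rubin-pooled estimate over 5 imputation(s):
#>   estimate 0.60800, SE 0.02183 (within 0.000477, between 6.16e-33)

true_estimands(cfg)
#> $cif      0.6331111
#> $median   44
```

The generating mechanism puts the true day-100 cumulative incidence at
0.633. This dataset's complete-data estimate is 0.600 (SE 0.022); dropping
the records with missing aGvHD times under MAR halves the estimate's
numerator but not the competing events, collapsing it to 0.435 — the
classic complete-case underestimate — while type 1 predictive mean
matching recovers 0.608 with an honest pooled SE. `run_study()` repeats
this comparison over the full method × mechanism × fraction grid.

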
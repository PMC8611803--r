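---
title: "Imputing bounded event times in competing risks: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Imputing bounded event times in competing risks: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mibet)
```

## The setting

A cohort of transplant recipients is followed for three mutually exclusive
first events: acute graft-versus-host disease (aGvHD, cause 1), graft
failure before aGvHD (cause 2) and death before aGvHD (cause 3), with
administrative censoring at day 365 for everyone still event-free. The
estimands are the cause-1 cumulative incidence at day 100,
$F_1(100) = \Pr(T \le 100, \text{cause} = 1)$, and the median time to
aGvHD, the first day at which $F_1$ reaches one half. The complication is
that some aGvHD onset *days* are missing while the diagnosis itself is
not: the time is interval-censored in $(L, R] = (0, 100]$ days. `mibet`
exists to study, by simulation, how multiple-imputation (MI) strategies
for those bounded times affect both estimands.

## The data-generating mechanism

Each subject draws a cause $j$ with probabilities $(p_1, p_2, p_3) =
(0.65, 0.25, 0.10)$ and an event day by inverse-transform sampling from a
cause-specific log-normal: with $u \sim U(0,1)$,
$t = \lceil \exp(\mu_j + \sigma_j \Phi^{-1}(u)) \rceil$, where
$(\mu_j, \sigma_j)$ are $(\log 26, \log 2)$, $(\log 43, \log 2)$ and
$(\log 77, \log 4)$ on the log-day scale. Days are integers (rounded up,
mirroring registry recording); times beyond day 365 become administratively
censored records. A binary auxiliary covariate (double vs single cord-blood
unit, Bernoulli(0.45)) is generated independently of everything — it is
deliberately uninformative, so that including it in an imputation model can
only add noise. These defaults *are* the study conditions; they are not
tuning knobs.

Because sampling inverts the conditional CDF, the marginal cause-1
incidence has the closed form
$F_1(t) = p_1 \, \Phi\{(\log t - \mu_1)/\sigma_1\}$, giving analytic truth
values: $F_1(100) = 0.6331$ and a median of 44 days (integer convention)
or 43.31 days (continuous root). See "Two median truths" below.

Missingness mechanisms (`apply_mdm()`):

* **MCAR** flags every record independently with the chosen probability,
  regardless of event type — the scenario used to check that complete-case
  analysis is unbiased when missingness carries no information.
* **MAR** flags only aGvHD records, independently with the chosen
  probability: missingness depends on the (always observed) event type but
  not on the time itself.
* **MNAR** flags the $\lfloor f \cdot n_1 \rfloor$ smallest aGvHD times
  (or largest, for the sensitivity variant), deterministically given the
  data; ties are broken by subject id and no random numbers are consumed.

Flagged records keep their generated time in a `true_time` column that
estimators and imputers never read; exported "analysis view" CSVs blank
the field entirely.

What the generator does *not* emulate: covariate-dependent hazards,
informative or staggered censoring, measurement error in the observed
times, more than three causes, and any correlation between the auxiliary
variable and outcome. Conclusions from the simulation therefore speak to
the mechanism structure, not to every feature of real registry data; in
particular the auxiliary-variable scenarios only measure the *cost* of an
uninformative auxiliary covariate, not the benefit of an informative one.

## Estimators

`cuminc_aj()` implements the Aalen-Johansen product-limit estimator on the
grid of observed event times, aggregating ties within a day before
updating the risk set and removing same-day censorings after the events.
Its pointwise variance is the Greenwood-style (Marubini–Valsecchi)
three-term sum; with one cause and no censoring it collapses to the
binomial Greenwood variance, and on censored competing-risks fixtures it
agrees with `survival::survfit`'s multistate standard errors to machine
precision (the test suite asserts both, plus agreement with a
nonparametric bootstrap within 10% at n = 500). Evaluation is
right-continuous (`cif_at()`); a jump exactly at the horizon is included
by default, with `include_at = FALSE` available because day-100 events
coinciding with the day-100 horizon are a genuine edge convention.

The median is the first jump time with $\hat F \ge 0.5$ and is `NA` — a
value, not an error — when the curve never gets there. Its standard error
divides $SE\{\hat F(\hat t_{50})\}$ by a local gradient
$(\hat F(\hat u_{50}) - \hat F(\hat l_{50}))/(\hat u_{50} - \hat l_{50})$
with anchors at the first jump above $0.5 + \epsilon$ and the last at or
below $0.5 - \epsilon$, $\epsilon = 0.01$ by default: large enough to span
several day-level jumps at n = 500, small enough to stay local. When an
anchor does not exist the SE is `NA` with a warning, and pooling or the
harness counts the replicate rather than dropping it silently.

## Imputation engines

All regression-based engines share one imputation model per completed
dataset: a Bayesian linear regression of the event time (log time for
LOGNORM) on an intercept, indicator contrasts for causes 2 and 3 (aGvHD is
the reference) and optionally the auxiliary covariate, fitted to all
records with an *observed event time*. Administratively censored records
are excluded from the regression: their times are follow-up horizons, not
event times, and including them would inflate the residual variance; they
are never missing themselves, so nothing needs predicting for them. This
was a genuinely open choice (one could add a fourth indicator level) and
is the package's position. Each imputation takes one posterior draw
($\sigma^{*2} = SSE/\chi^2_{h-q}$,
$\beta^* \sim N(\hat\beta, \sigma^{*2}(Z'Z)^{-1})$) and then:

* **NORM** draws $z_i\beta^* + \sigma^* e_i$ with no restriction — values
  below 0 or above 100 are possible and retained, which is the method's
  documented pathology, not a bug.
* **LOGNORM** does the same on the log scale and exponentiates.
* **RESNORM** redraws the residual (keeping $\beta^*, \sigma^*$) until the
  value lands in the record's $(L, R]$ or a cap (default 200, alternative
  500) is reached; on exhaustion the last draw is kept and counted in an
  out-of-bounds counter reported per run.
* **PMM** (types 0/1/2) matches each incomplete record to the
  `donor_pool_size = 5` observed records with the closest predicted mean —
  type 1, the default, compares $\beta^* z_i$ with $\hat\beta z_h$ — and
  copies a randomly chosen donor's observed time. Because the predictors
  are categorical, distances tie in blocks; ties are broken by a single
  random permutation of donors per imputation, which is reproducible under
  the seed and favours no donor systematically. Five is the conventional
  donor-pool default of standard MI software; nothing in the study design
  pins it otherwise.
* **MICI** initialises each missing time from the observed cause-1 times
  inside its bounds and then iterates (10 cycles by default): re-estimate
  the cause-1 Aalen-Johansen curve on the completed data, then resample
  each missing time from the observed cause-1 days within $(L_i, R_i]$
  with probability proportional to the current CIF jump sizes. Ten cycles
  and empirical-distribution initialisation are package choices — the
  iteration is a fixed-point refresh whose sampling weights stabilise
  within a few cycles at these sample sizes — and both are exposed in
  `imp_spec()`.

PMM and MICI can only produce observed cause-1 times (the subset
property); RESNORM with cap 500 leaves no value out of bounds in the
default scenarios. Both facts are asserted in the test suite.
`complete()` writes imputed values back *unrounded*: the estimators handle
non-integer times, and re-ceiling would add a second, silent rounding
mechanism to the study.

## Pooling and performance measures

`pool_rubin()` applies Rubin's rules with no small-$m$ degrees-of-freedom
adjustment, since the study reports standard errors rather than
confidence intervals. Imputations with undefined estimates are dropped
and counted; a pooled result needs at least two.

The harness (`run_study()`) reports, per method × mechanism × fraction ×
estimand: the mean estimate, the empirical SD across replicates, the
standardized bias $(\bar{\hat\beta} - \beta)/SD(\hat\beta)$ and the
average model-based SE $\sqrt{\sum_k SE_k^2 / K}$. Replicates are seeded
as `base_seed + replicate`, so every method within a replicate sees an
identical incomplete dataset and method contrasts are paired; each
(replicate, method) pair then gets its own derived stream for the
imputation draws, making results invariant to the order in which cells
are run.

## Two median truths

On day-rounded data the median *estimator* can only return integers, and
its replicate mean sits about 0.8 days above the continuous root of the
true mixture CDF (43.31 days) even with complete data — roughly a 0.2 SD
offset shared by every method. Both conventions are therefore available
and used deliberately:

* `median_convention = "continuous"` (the `run_study()` default for the
  bias denominator's reference) measures distance from the point where
  the true incidence crosses one half. This is the convention under which
  the benchmark complete-case MCAR results were evidently computed, and it
  is the right scale for comparing against them.
* `median_convention = "ceiling"` (the `true_estimands()` default, 44
  days) is the true median of the *discrete* day distribution the
  generator actually produces, and is the right reference when the
  question is method-specific bias net of the rounding offset: the
  property checks of the qualitative method ranking use it.

Neither convention is "the" truth; the vignette states both so results are
read on the intended scale.

## Numerical choices and degenerate inputs

* Quantile inversion rounds at $10^{-9}$ before ceiling so that exact
  quantiles (e.g. $\exp(\log 26)$) are not pushed up a day by floating
  point.
* If a whole risk set fails at one time, the Greenwood sum's degenerate
  term is dropped (its weight is zero at that point) and the SE carries
  forward with a warning.
* A predictor level with no observed-outcome rows is dropped from the
  design with a warning; a rank-deficient design is an error naming the
  columns.
* An MNAR fraction too small to flag a single record warns and flags
  nothing.
* MICI's fallback when no candidate day lies inside a record's bounds is
  the interval midpoint, with a warning; in the default scenarios the
  candidate set is never empty.

## Problem sizes

The package's own acceptance checks run the calibration, the MCAR
complete-case cells, and the reversed-MNAR cells at the study's full 1000
replicates of n = 500; the qualitative method-ranking grid runs its
non-PMM cells at 300 replicates (the asserted contrasts are 0.5–2 SD
against a Monte-Carlo error of about 0.06) and the PMM bias cells at the
full 1000. `scripts/acceptance.R` recomputes the headline quantities at
1000 replicates in about a minute.

## Known limitations

* The auxiliary covariate is noise by construction; the NOAUX contrasts
  quantify only the price of an uninformative auxiliary variable.
* MICI's within-imputation SEs come from the standard estimators on
  completed data, so its pooled SE understates the true sampling
  variability (visible in the harness as average model SEs at or below
  the full-data level) — a property of the method, reproduced rather
  than repaired.
* No Fine-Gray or covariate-adjusted modelling; estimands are marginal.
* Semiparametric likelihood approaches to interval-censored competing
  risks (B-spline sieve estimators, NPMLE) are outside the package's
  scope.
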
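---
title: "Projecting excess NCD mortality under disrupted treatment coverage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Projecting excess NCD mortality under disrupted treatment coverage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ncdexcess)
```

## The problem

Armed conflict disrupts the routine care that keeps people with chronic
non-communicable diseases (NCDs) alive: dialysis sessions are missed,
insulin cold chains break, cancer surgery stops, and acute cardiac and
stroke care becomes unavailable. `ncdexcess` implements a discrete-time
cohort microsimulation that projects the *excess* mortality attributable
to such treatment disruption — deaths above the counterfactual level that
would have occurred without the crisis — for a set of high-burden NCDs
(ischaemic heart disease, stroke, dialysis-dependent chronic kidney
disease, type-1 diabetes, and common cancers) under user-defined scenarios
of treatment coverage.

## Model

For each disease $u$, excess deaths at month $t$ are

$$D_{u,t,\mathrm{excess}} = D_{u,t,\mathrm{crisis}} - D_{u,t,\mathrm{base}},$$

where both arms are produced by the same cohort ledger under different
treatment-coverage paths. Each month since January 2000, an incident
cohort enters (Poisson-distributed around a calibrated mean); a cohort of
age $\tau$ months since onset loses, during month $t$, a fraction

$$c_t\, q_T(\tau) + (1 - c_t)\, q_U(\tau)$$

of its survivors, where $c_t$ is coverage (the proportion of cases
receiving appropriate care) and $q_\sigma(\tau) = 1 -
S_\sigma(\tau+1)/S_\sigma(\tau)$ is the monthly death probability implied
by the treated/untreated survival function. Treatment status is thus a
per-month mixture at rate $c_t$, not a fixed assignment at onset; this
matches the prevalence-integral formulation of the model, in which each
time step applies coverage to the whole prevalent pool. Cohorts are
retired at `tau_max`.

Four parametric survival families are supported, with per-month hazards

* exponential: $\mu(\tau) = \lambda$;
* Weibull: $\mu(\tau) = (k/s)(\tau/s)^{k-1}$;
* log-normal: $\mu(\tau) = \phi(z)/(\sigma\tau(1-\Phi(z)))$,
  $z = (\ln\tau-\mu)/\sigma$;
* log-logistic: $\mu(\tau) = (\beta/\alpha)(\tau/\alpha)^{\beta-1} /
  (1+(\tau/\alpha)^\beta)$.

Each hazard is paired with its closed-form survival function so that
$\mu = -\mathrm{d}\ln S/\mathrm{d}\tau$ holds exactly; for the log-normal
this means the standard hazard with the $1/(\sigma\tau)$ Jacobian, which
is the only form consistent with log-normal survival. The discrete
monthly death probability is tested against adaptive quadrature of the
hazard to $10^{-8}$.

**Acute cardiovascular branch.** For ischaemic heart disease and stroke,
the first acute presentation carries an immediate death risk
$\mu_{\mathrm{acute}}$ (treated or untreated, mixed by coverage); acute
survivors enter the chronic ledger under hazards *conditioned on acute
survival* — published overall survival at time $\tau$ is divided by
$1-\mu_{\mathrm{acute}}$ before fitting, and
`condition_on_acute_survival()` enforces the implied bound on the
observations.

**Prevalent pool.** Type-1 diabetes is modelled without incidence: a
recorded prevalent pool at crisis onset depletes month by month under the
coverage-mixed hazards, with time since exposure counted from crisis
onset (individual durations are unknown; the default untreated hazard is
time-constant, so the choice is immaterial at this horizon). Baseline
type-1 diabetes mortality is taken as zero, reflecting near-universal
pre-crisis insulin coverage, so its counterfactual arm contributes
essentially no deaths.

## Fitting survival curves

Published cohort studies report proportions surviving at a handful of
follow-up times, not individual-level data. `fit_survival_model()`
therefore maximises an independent-binomial likelihood
$\sum_i x_i \ln S(\tau_i) + (n_i - x_i)\ln(1-S(\tau_i))$ with
$x_i = \mathrm{round}(n_i s_i)$ and an effective cohort size $n_i$
(default 100 when the source reports none — a deliberately weak weight).
Treating time points as independent ignores the nesting of survivors
within one cohort; it is an acknowledged approximation forced by the data
format. Families are ranked by raw maximised log-likelihood; an AIC
option exists but is off by default, since with few points the parameter
penalty tends to override the data. Optimisation runs on log-transformed
positive parameters (location stays on the real line for the log-normal)
from a deterministic multi-start grid anchored at the empirical median
survival time, with Nelder–Mead followed by a BFGS polish at relative
tolerance $10^{-12}$; two-parameter families require at least two
distinct follow-up times and are otherwise skipped with a warning. Where
two source studies disagree, both are kept as lower/upper bound curves.

## Counterfactual baseline and calibration

The no-crisis death series is forecast from pre-crisis annual counts with
a Poisson GLM (log link, year as the single predictor, centred at the
first data year); with two years of data the fit interpolates both counts
exactly, and a single year yields a flat forecast with a warning. The
annual forecast is divided by 12 into the month whose start day falls in
that calendar year. Forecasts are deterministic point forecasts: the
model propagates uncertainty through coverage and survival bounds only,
so GLM sampling error is deliberately not propagated. A combined stroke
series can be split 50/50 into ischaemic and haemorrhagic at load, and a
plain population-ratio multiplier is available where the baseline series
comes from a neighbouring region.

The mean monthly incidence $I$ of each disease is then calibrated: the
expected counterfactual ledger is linear in $I$, so the multiplier
$k$ is the ratio of the forecast to the simulated mean over the final 12
pre-crisis months, computed in expectation mode at the midpoint of the
pre-crisis coverage range (0.90–1.00 by default). Computing $k$ from
expectations rather than stochastic runs keeps it free of Monte-Carlo
noise; the residual approximation — evaluating at the coverage midpoint
rather than averaging over the uniform draw — is second-order in the
range width and is verified in the tests to stay inside 3 Monte-Carlo
standard errors of the stochastic counterfactual.

## Uncertainty propagation and pairing

Each of `n_runs` (default 1000) runs draws, per disease: one uniform
quantile per analysis period (mapped through the crisis arm's coverage
range *and* the counterfactual arm's baseline range — both arms share the
quantile), one Uniform(0,1) weight mixing the lower/upper survival-bound
curves, the Poisson incident-case series, and a seed for the binomial
death draws that is reused by both arms. These common random numbers make
the paired difference exactly zero when crisis ranges equal baseline
ranges and minimise the variance of the excess otherwise. Summaries
report the mean and the empirical 2.5th/97.5th percentiles (linear
interpolation) across runs; negative per-run excess is retained. Deaths
are binomial draws per cohort-month; the model only requires Poisson
incidence sampling, and binomial deaths are this package's choice of
within-run demographic noise. An *expectation mode* replaces every draw
by its mean and serves as the deterministic oracle in tests.

Age is handled by allocation rather than stratification: hazards and
coverage are assumed age-independent, so the ledger is linear in
incidence and simulating the total then allocating deaths by each
disease's fixed age distribution is exactly equivalent to per-stratum
simulation (a tested invariant). The age distribution of deaths is
assumed unchanged by the crisis — an approximation that shifts slightly
young-ward as survival shortens, negligible over a ten-month horizon.

## Time conventions and key parameters

| parameter | default | meaning |
|---|---|---|
| `dt` | 1 month | simulation step |
| grid origin | Jan 2000 | first incident cohort (burn-in start) |
| `war_start` | month 285 | crisis onset (Oct 2023 on the default grid) |
| periods | 4 + 3 + 3 months | "to date", projection months 1–3, 4–6 |
| `tau_max` | burn-in length (285) | cohort retirement age, configurable |
| baseline coverage | 0.90–1.00 | pre-crisis essential-treatment coverage |
| `n_runs` | 1000 | Monte-Carlo runs per scenario |
| `phi_incidence`, `phi_cfr` | 1 | crisis relative-risk hooks |

Months follow a 7th-to-6th convention so that analysis periods starting
on the 7th of a month align exactly with grid months. All hazard
parameters are converted to per-month units at load — yearly rates are
divided by 12, Weibull/log-logistic scales multiplied by 12, log-normal
locations shifted by $\ln 12$ — and a missing unit label on survival
parameters is an error, never a silent default. The upper limit
`tau_max` of the prevalence integral is not pinned down by the model
statement; the default retires cohorts at the burn-in length, so the
oldest tracked case at crisis onset dates from the grid origin, and the
value is configurable. The relative-risk hooks $\phi$ are exposed but
default to 1: treatment disruption is assumed to be the only pathway
from crisis to excess death, which understates risks acting through
incidence or severity.

## The synthetic-data generator

`generate_inputs()` produces a complete input bundle with known ground
truth: log-linear annual death series with Poisson noise (six baseline
years), hazard families per arm in which the untreated curve dominates
the treated one at every $\tau$, bound pairs for some arms, uniform
coverage ranges nested pointwise ceasefire ≥ status quo ≥ escalation
above a shared "to date" range, a fixed prevalent pool of 2000 for the
insulin-dependent disease, and a nine-stratum population. Magnitudes are
set so monthly death totals are of order $10$–$10^3$, the scale of a
population of a few million. The `paper_like` profile uses the full
January-2000 grid, five disease groups and 1000 runs; the `small` profile
(three diseases — one per structural kind — and a 3-year burn-in) exists
so the test suite runs in seconds.

The ground truth includes analytic expected deaths computed by
`oracle_expected_deaths()`, a direct cohort-by-cohort convolution using
cumulative products of closed-form survival — deliberately a separate
code path from the engine's month-stepping ledger. The expectation-mode
pipeline reproduces these values to machine precision, and full
stochastic runs cover them within the 95% percentile intervals.

The generator is structural, not empirical: it does not reproduce any
real region's parameter values, registry coding practice, reporting
gaps, displacement dynamics, or correlated uncertainty between diseases.
Passing tests on synthetic bundles therefore demonstrates that the
machinery is correct under the model's own assumptions, not that any
particular real-world projection is accurate — that depends entirely on
the quality of the supplied baseline series, survival parameters and
coverage ranges.

## Numerical choices and degenerate inputs

* Survival at $\tau = 0$ is exactly 1 for every family; hazards are
  defined for $\tau > 0$ only, and $\tau \le 0$ is a domain error.
* Tiny negative monthly death probabilities from floating-point
  cancellation are clamped to 0; probabilities are capped at 1 after any
  $\phi$ scaling.
* An all-zero baseline series forecasts zero deaths (guarded $-\infty$
  intercept); a zero calibration target yields $k = 0$ with a warning
  and a dead counterfactual arm, which is the correct structural answer
  for the type-1 diabetes baseline.
* Counts are rounded half-up, with thousands separators, only when
  report tables are written; all upstream arithmetic is on reals.
* `validate_bundle()` is pure and returns messages rather than throwing;
  a treated curve exceeding the untreated one is reported at warning
  level, since treatment benefit is an assumption of the model rather
  than a mathematical requirement.

## Problem sizes used in the tests

Unit tests run the `small` profile (46-month grid) with tens to hundreds
of runs. The acceptance-style checks run, among other things: the
paired-arm zero-excess identity at 50 runs; calibration self-consistency
at 200 runs against 3 Monte-Carlo standard errors; survival-family
selection over 100 replicates at effective cohort size $10^4$; baseline
slope recovery over 500 replicates; and one full `paper_like` study —
five diseases, three scenarios, 1000 runs on the 295-month grid — whose
stochastic means are compared with the analytic ground truth. These
sizes were chosen to make Monte-Carlo error bars meaningful while
keeping a complete test run in a few minutes on one core.

## Known limitations

Treatment is binary (full care or none) with no partial-adherence state;
hazards, coverage and calibration are age-independent; no sex
stratification; no repeat acute events, disease-progression stages, or
comorbidity structure; incidence is constant over the horizon apart from
the calibration constant; GLM forecast uncertainty is not propagated.
All of these push the projections toward understatement in a real
crisis, and the package should be read as a scenario-projection tool,
not a forecast.
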
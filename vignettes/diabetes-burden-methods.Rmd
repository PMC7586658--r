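---
title: "Methods: projecting the burden of type-2 diabetes in an aging population"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: projecting the burden of type-2 diabetes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmburden)
```

# Overview

`dmburden` projects three facets of the burden of type-2 diabetes (DM2) in
an elderly population: the growth of the diabetic population and its
doubling time, the diabetic share of hospitalization and outpatient costs,
and the years of life lost to diabetes at age 60. The estimation layer is
designed for a longitudinal survey of community-dwelling elderly with
sampling weights, self-reported diabetes with age at diagnosis, and
registry-linked mortality follow-up with cause-of-death flags; a synthetic
generator emulates exactly such a study so that every estimator has a known
recovery target.

All age-indexed quantities live on an abridged grid of 5-year groups ending
in an open 95+ group (`age_grid()`). Adult modelling starts at age 30:
self-reports of a diagnosis before 30 are treated as type-1 disease and
excluded.

# Rate estimation

Prevalence, incidence and diabetic mortality are estimated as weighted
occurrence/exposure (person-years) rates per age group. This is equivalent
to a saturated piecewise-exponential model per age group fitted by maximum
likelihood; with no covariate structure specified for the projection inputs,
the saturated age-group model is the minimal faithful choice.

Two exposure windows are available for incidence:

* **retrospective** (default): history is reconstructed from the reported
  age at diagnosis under a no-survival-selection assumption. Every subject
  contributes diabetes-free exposure from age 30 to the earlier of diagnosis
  and baseline age, and prevalent diagnoses are the events.
* **follow-up**: diabetes-free subjects contribute prospective person-years
  until incident diagnosis, death or the end of follow-up.

These two windows estimate different quantities when the diagnosis-age
distribution of prevalent cases is not generated by the stationary incidence
process. In the synthetic generator the diagnosis ages of prevalent cases
are imputed uniformly between 30 and the baseline age — a deliberately
uninformative choice, since a survey only asks for the diagnosis age and
gives no basis for a sharper model. Consequently only the **follow-up**
window recovers the generator's incidence schedule, and the
parameter-recovery tests use it; the retrospective window is validated
against hand-enumerated person-years instead.

Central rates convert to interval probabilities through the separation-
factor relation \(q = n m / (1 + (n - a) m)\), capped at 1, with \(a = n/2\)
by default for closed elderly bins (model-life-table separation factors
matter mainly at infant ages; they can be supplied for tables from birth,
where the first group defaults to 1.5 years). The open group takes
\(q = 1\).

Cause-specific hazards for the competing-risks step share one person-years
denominator, so the diabetes-caused and other-caused rates sum exactly to
the all-cause rate.

# The population projection

The projection recurrence reads, cohort-wise,

\[
N_{x+t}^{d}(Y+t) \;=\; N_x^{d}(Y)\,\bigl(1 - {}_td_x\,{}_tq_x\bigr)
  \;+\; N_x(Y)\,{}_td_x ,
\]

with \({}_td_x\) the \(t\)-year cumulative diagnosis risk and \({}_tq_x\)
the interval death probability of the diabetic population.
`back_project()` solves this recurrence backwards (the form in which it is
usually printed) and `forward_project()` runs it forwards; the two are exact
algebraic inverses, which the tests verify to \(10^{-6}\). Several points
were genuinely open and are resolved as follows:

* **Time indexing.** The recurrence is read cohort-wise: the diabetic
  population aged \(x+t\) at year \(Y+t\) descends from the population aged
  \(x\) at year \(Y\). A same-year reading would compare unrelated cohorts.
* **Denominator probability.** The death probability is that of the
  *diabetic* population by default; `formula_qx = "allcause"` runs the
  alternative reading with general-population mortality.
* **Annual-to-interval conversion.** Annual incidence \(h\) converts to
  \({}_td_x = 1 - \exp(-t h)\). Scenario multipliers scale the annual rate
  before conversion.
* **Open terminal group.** No one ages out of 95+: the group accumulates
  the outflow of 90–94 plus its own survivors. Going backwards this split
  is under-determined from one state; forward-projected states record the
  split (an `open_inflow` attribute) making the inversion exact, and raw
  observed states are closed by assuming the open group's prevalence equals
  the penultimate group's at the earlier year — exact when old-age
  prevalence is age-flat, and an explicit approximation otherwise.
* **Negative numerators** (possible at the oldest ages when the incidence
  subtraction exceeds the surviving descendants) are floored at zero with a
  warning naming the group; fractional persons are never rounded before
  report time.
* **Ages 30–59** carry no survey information; their prevalence, incidence
  and mortality come from a national-style table (`fill_rate_table()`),
  with general-population all-cause mortality standing in for diabetic
  mortality at those ages. Missing elderly cells propagate as missing and
  must be filled — never silently zeroed.

Doubling time assumes constant linear (arithmetic) growth: the annualized
growth \(r\) is the mean of per-period slopes of the diabetic 60+
population, and the doubling time is the reference-year population divided
by \(r\). It is invariant to rescaling all counts, reported to the nearest
half-year with the raw value alongside, and a non-positive slope is
signalled (`no_doubling`) rather than thrown. The scenario sweep multiplies
annual incidence by each factor in \(\{0.25,\dots,1.75\}\) and re-runs the
projection under otherwise identical assumptions; population size at the
horizon must increase, and doubling time must not increase, with the
multiplier — which the test suite asserts.

The projection-level Monte-Carlo oracle (`simulate_projection_step()`)
realizes the recurrence at the individual level: each person draws a
new-diagnosis Bernoulli event with probability \({}_td_x\) and each
prevalent diabetic is removed with the recurrence's attrition probability
\({}_td_x {}_tq_x\). Its expectation equals the deterministic recurrence
exactly, so back-projection must recover a microsimulated baseline within
binomial noise. Note what this does and does not show: it validates the
aggregation, grid alignment and inversion bookkeeping against independent
per-person simulation, not the demographic fidelity of the recurrence
itself — the recurrence is not the inverse of a continuous-time
illness-death model, and it is implemented as printed.

# Two-part cost models

Annual utilization of hospitalizations and outpatient consultations follows
the health-economics two-part decomposition: a logistic model for any use
in a calendar year (annual counts avoid seasonality bias by construction)
and a positive-part intensity among users. The expected annual episodes per
(diabetes status × age band) stratum are computed with both parts saturated
by stratum, so they equal the stratum empirical means exactly — an identity
the tests assert; the regression coefficients (diabetic indicator plus
60–69 / 70–79 / 80+ band indicators) summarize the same data and are the
recovery targets for the synthetic generator, whose positive part is
\(1 + \text{Poisson}(\mu)\) with log-linear \(\mu\). A log-linear intensity
fit is available (`intensity = "loglinear"`) and is the one compared against
the generating coefficients. Strata with all-zero or all-positive use are
reported as separation and fall back to empirical means.

Costs attach at the episode level through a unit-cost table (2011 USD per
episode, provider perspective — unit costs constructed as total service
expenses over total production); per-capita cost is episodes × unit cost,
and projected totals apply constant per-capita patterns to the projected
diabetic and non-diabetic counts. The diabetic share of total cost is
invariant to rescaling unit costs and, under constant patterns, rises
exactly when projected prevalence rises — both tested.

# Lee-Carter forecasting

The mortality model is the classical log-bilinear decomposition
\(\log m(x,t) = a_x + b_x k_t + \varepsilon\), estimated from scratch:
\(a_x\) as row means of the log rates, \((b_x, k_t)\) from the first
singular component of the centred matrix, normalized to
\(\sum_x b_x = 1\), \(\sum_t k_t = 0\), with the sign fixed so
\(\sum_x b_x > 0\). A degenerate (time-constant) surface returns a flagged
flat fit rather than an error. The second-stage adjustment that re-solves
each \(k_t\) to match observed total deaths is implemented and switches on
automatically when deaths and exposures accompany the surface; it is off
otherwise, since the exact second-stage options used by any given published
forecast are rarely stated.

The period index is forecast as a random walk with drift,
\(\hat d = (k_T - k_1)/(T-1)\), innovation standard deviation estimated
from first differences. Simulation-based forecasting (default 1,000
trajectories) resamples the drift from its estimation distribution
(`drift_uncertainty = TRUE`) — drift error dominates long-horizon
uncertainty and omitting it understates interval width. Median and
percentile surfaces are computed from the simulated rates themselves, not
from an analytic formula. Fitting windows matter: decades with atypically
steep declines (e.g. the tail of an infant-mortality transition) should be
excluded with `window_surface()` / the `years` argument, which is why the
default synthetic surface spans 1980–2010 and forecasts 25 years to 2035.

# Life tables, cause deletion and years of life lost

`life_table()` builds standard abridged tables (radix 100,000, open group
closed by \(L = l/m\)). Three counterfactual schedules feed the diabetes
scenarios: all-cause; proportional deletion \(m(1-f)\) with \(f\) the
age-specific registry fraction of deaths attributed to diabetes (zero below
30, held constant over forecast time); and deletion plus re-insertion
\(m(1-f) + h\) of a model-based diabetes-caused hazard \(h\) from the
competing-risks estimator. Years of life lost at 60 is
\(e_{60}^{\text{all}} - e_{60}^{\text{delete+reinsert}}\); it can be
negative when \(h < f m\) and is then reported with a message, never
clipped. When \(h\) exceeds the deleted mortality the scenario ordering
\(e_{60}^{(3)} < e_{60}^{(1)} < e_{60}^{(2)}\) follows from hazard
monotonicity, and the suite asserts it.

Two orders of operations are possible for the counterfactual life
expectancies: fit-and-forecast a cause-deleted surface, or apply
deletion/re-insertion to the forecast all-cause schedule at the target
year. The package uses the first for the life-expectancy-at-birth pair of
forecasts (two independent streams) and the second for the \(e_{60}\)
scenarios, matching the hazard-arithmetic description of the
delete-and-reinsert construction; both orders remain available through the
exported functions.

Interval estimates for \(e_{60}\) and the years of life lost are percentile
intervals across forecast trajectories (`yll_confidence_interval()`,
`e60_scenario_table()`); interval reporting refuses fewer than 100
trajectories. A repeated-seed experiment in the test suite (200 replicates,
300 trajectories each) checks that nominal 95% intervals cover the
generator's realized-future value at close to the nominal rate.

# The synthetic generator

`generate_cohort()` emulates a nationally representative elderly panel:
2,827 subjects by default, baseline 2005, ages 60–104 thinning at about 8%
per year of age, 52.5% female, lognormal sampling weights normalized to
mean 1 (dispersion 0.3), age-specific baseline prevalence averaging about
21%, annual diagnosis rates declining from 1.2% to 0.3% across the elderly
groups, Gompertz-like baseline mortality, a diabetes mortality hazard ratio
of 1.6, 30% of diabetic deaths certified to diabetes, and 12 years of
follow-up (a 2005 baseline linked through 2017). Follow-up is a
piecewise-exponential illness-death simulation with hazards constant within
5-year bins. One integer seed drives each call; repeated calls are
bit-identical.

What the generator does *not* emulate: survey design effects beyond
independent lognormal weights, covariate structure (education, BMI,
smoking and similar fields drive nothing), measurement error in
self-reports, or migration. Passing recovery tests therefore demonstrate
internal consistency of estimator and generator under clean sampling — not
robustness to the complications of real survey data.

`generate_mortality_surface()` realizes the log-bilinear model with a
random-walk-with-drift period index (defaults: drift −0.5, innovation SD
0.4, observation noise 0.01 on the log scale, 1980–2010) plus an
age-specific diabetes death-fraction table (zero below 30, up to ~6% at
old ages). `generate_utilization()` draws counts from the two-part model
with hospitalization rare (participation about 9% among non-diabetic
sexagenarians) and outpatient care near-universal, diabetic excess in both
parts.

# Problem sizes and numerical choices

Parameter-recovery tests run at cohort size 50,000 (rates) and 20,000
(two-part models), with 3 standard-error tolerances; the microsimulation
inversion check uses 100,000 persons in five elderly groups so that a 2%
per-group tolerance corresponds to more than three binomial standard
errors; the coverage experiment uses 200 replicates of 300 trajectories.
These sizes keep the full suite under a few seconds while leaving
Monte-Carlo error well inside every tolerance. Tie-breaks and degenerate
inputs are handled explicitly: empty rate cells propagate as `NA`, a
constant surface yields a flagged flat fit, zero-slope growth yields
`no_doubling`, and `q` caps at 1.

# Known limitations

* The projection recurrence is implemented as printed; its incidence term
  applies to the total population of the source age group, which can
  overstate accumulation when prevalence is high — visible in synthetic
  runs as a steeper prevalence path than a compartmental illness-death
  model would give.
* The open-group closure for back-projection from raw states is exact only
  under age-flat old-age prevalence.
* Two-part models carry no covariates beyond diabetes status and age band;
  no discounting, inflation, out-of-pocket perspective or indirect costs.
* The Lee-Carter implementation is the base method: no cohort effects, no
  jump-off correction, no multi-population coherence.
* Cause fractions and the model-based diabetes hazard are held constant
  over forecast time by assumption.
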
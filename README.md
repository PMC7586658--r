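# dmburden

Projection machinery for the burden of type-2 diabetes (DM2) in an aging
population, written for epidemiologists and health economists working with
longitudinal elderly cohorts. The package covers four linked analyses:

1. **Rates.** Weighted occurrence/exposure estimation of age-specific
   diabetes prevalence, incidence (from reported age at diagnosis or from
   prospective follow-up), diabetic all-cause mortality, and cause-specific
   hazards under competing risks, on an abridged 5-year age grid ending in
   an open 95+ group.
2. **Population projection.** The cohort-wise recurrence

   N<sub>x</sub><sup>d</sup> = [N<sub>x+t</sub><sup>d</sup> −
   N<sub>x</sub>·<sub>t</sub>d<sub>x</sub>] /
   (1 − <sub>t</sub>d<sub>x</sub>·<sub>t</sub>q<sub>x</sub>)

   run backwards and forwards (exact inverses), with linear-growth doubling
   times and incidence scenario sweeps (multipliers 0.25–1.75).
3. **Costs.** Two-part (participation × intensity) models of annual
   hospitalization and outpatient utilization, per-capita costs via unit
   cost tables (2011 USD per episode), and projected diabetic cost shares
   under constant utilization patterns.
4. **Mortality and years of life lost.** From-scratch Lee-Carter estimation
   (log m(x,t) = a<sub>x</sub> + b<sub>x</sub>k<sub>t</sub>, SVD, random
   walk with drift) with simulation-based forecasts and percentile
   intervals; abridged life tables with proportional cause deletion and
   competing-risks hazard re-insertion; years of life lost to diabetes at
   age 60 with forecast-based confidence intervals.

A synthetic-data module generates every input — cohort, utilization,
mortality surface, population counts — from known ground-truth parameters,
so each estimator has a recovery target and the whole pipeline runs without
any external data.

## Worked example

```r
library(dmburden)

## a synthetic elderly cohort of the usual survey size
ch <- generate_cohort(cohort_spec(n_subjects = 2827, seed = 42))
prev <- estimate_prevalence(ch, age_grid(60, 95))
round(prev$prevalence, 3)
#> [1] 0.227 0.240 0.258 0.248 0.211 0.168 0.234 0.165

## an abridged life table from a Gompertz-like elderly schedule
mx <- c(0.010, 0.016, 0.025, 0.040, 0.065, 0.105, 0.170, 0.280)
lt <- life_table(mx, age_grid(60, 95))
life_expectancy(lt, 60)
#> [1] 22.96025

## Lee-Carter fit and stochastic forecast on a synthetic 1980-2010 surface
surf <- generate_mortality_surface(surface_spec(seed = 42))
fit <- lc(surf, years = c(1980, 2010))
fit
#> Lee-Carter fit: 20 age groups, 31 years ( 1980 - 2010 )
#>   drift -0.4719 (se 0.0944), innovation sd 0.5170
#>   first singular component explains 99.9% of variance

## years of life lost to diabetes at 60 in 2025, with forecast uncertainty
fc <- lc_forecast(fit, horizon = 25, n_sims = 1000, seed = 42)
f  <- attr(surf, "truth")$diabetes_fraction_by_age   # registry fractions
h  <- ifelse(surf$grid$age_start >= 60, 0.08 * exp(fit$ax), 0)
ci <- yll_confidence_interval(fc, f, h, year = 2025)
sprintf("YLL at 60 in 2025: %.3f (%.3f-%.3f) years", ci$median, ci$lower, ci$upper)
#> [1] "YLL at 60 in 2025: 0.613 (0.491-0.752) years"
```

The prevalence vector is the weighted proportion diabetic per 5-year age
group (about 21% overall, the level the synthetic defaults emulate). The
life expectancy of 22.96 years is e60 for the stated schedule. The
forecast drift of −0.47 per year is the estimated annual decline of the
mortality index; 0.613 years — roughly seven months — is the life
expectancy at 60 lost to diabetes under the delete-and-reinsert
counterfactual, with a 95% interval from the 1,000 simulated mortality
trajectories.

`run_pipeline(run_config(seed = 1), outdir = "out")` executes the whole
chain — generate, estimate, back/forward project, cost projection,
two-stream forecast, scenario life tables — and writes scenario, series,
cost and life-table CSVs plus a YAML manifest.

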
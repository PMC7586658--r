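# A well-behaved elderly rate table and baseline for projection tests.
proj_rates <- function(grid = grid30, incidence = 0.008) {
  ages <- grid$age_start
  m <- 0.004 * exp(0.07 * (ages - 30))
  rate_table(grid,
             prevalence = pmin(0.25, 0.02 + 0.003 * (ages - 30)),
             incidence = rep_len(incidence, nrow(grid)),
             m_diabetic = m,
             q_diabetic = mx_to_qx(m, grid$age_width),
             source = "assumed")
}

proj_state <- function(grid = grid30, year = 2006, per_group = 10000,
                       prev = 0.18) {
  # age-flat diabetes prevalence at the old ages keeps the open-group
  # closure of the back-projection exact
  population_state(year, grid, rep(per_group, nrow(grid)),
                   rep(per_group * prev, nrow(grid)))
}

test_that("zero incidence reduces back-projection to the identity", {
  rt <- proj_rates(incidence = 0)
  st <- proj_state()
  totals <- flat_totals(grid30, seq(1991, 2006, by = 5), 10000)
  prev <- back_project(st, rt, totals)
  # N_x^d(Y - t) = N_{x+t}^d(Y) cohort-wise
  expect_equal(prev$n_diabetic[1:(nrow(prev) - 2)],
               st$n_diabetic[2:(nrow(st) - 1)])
  expect_equal(attr(prev, "year"), 2001)
})

test_that("applying back-projection twice walks 2006 -> 2001 -> 1996", {
  rt <- proj_rates()
  st <- proj_state(year = 2006)
  totals <- flat_totals(grid30, seq(1991, 2006, by = 5), 10000)
  s01 <- back_project(st, rt, totals)
  # at the oldest ages the incidence subtraction can exceed the surviving
  # descendants; the count is floored at zero with a warning naming groups
  s96 <- suppressWarnings(back_project(s01, rt, totals))
  expect_equal(attr(s01, "year"), 2001)
  expect_equal(attr(s96, "year"), 1996)
  expect_true(all(s96$n_diabetic >= 0))
})

test_that("forward and back projection are numerical inverses", {
  rt <- proj_rates()
  totals <- flat_totals(grid30, seq(1996, 2026, by = 5), 10000)
  st <- proj_state(year = 2006)

  # back then forward reproduces the state (prevalence-matching closure)
  back <- back_project(st, rt, totals)
  fwd <- forward_project(back, rt, totals, 2006,
                         entrant_prevalence = st$n_diabetic[1] /
                           st$n_total[1])
  rec <- fwd[[length(fwd)]]
  expect_lt(max(abs(rec$n_diabetic - st$n_diabetic) /
                  pmax(st$n_diabetic, 1)), 1e-6)

  # forward then back reproduces the state exactly (open split recorded)
  fwd2 <- forward_project(st, rt, totals, 2011)
  back2 <- back_project(fwd2[[2]], rt, totals)
  expect_lt(max(abs(back2$n_diabetic - st$n_diabetic) /
                  pmax(st$n_diabetic, 1)), 1e-6)
})

test_that("pure aging shifts diabetic cohorts up the grid", {
  g <- grid30
  rt <- rate_table(g, prevalence = 0.1, incidence = 0,
                   m_diabetic = c(rep(0, nrow(g) - 1), 0.2),
                   q_diabetic = c(rep(0, nrow(g) - 1), 1))
  nd <- seq_len(nrow(g)) * 100
  st <- population_state(2006, g, rep(1e4, nrow(g)), nd)
  totals <- flat_totals(g, c(2006, 2011), 1e4)
  # open-group mortality present (q = 1) but zero for closed groups
  out <- forward_project(st, rt, totals, 2011)[[2]]
  expect_equal(out$n_diabetic[2:(nrow(g) - 1)], nd[1:(nrow(g) - 2)])
})

test_that("the recurrence denominators and inputs are validated", {
  rt <- proj_rates()
  rt$incidence[3] <- NA
  st <- proj_state()
  totals <- flat_totals(grid30, seq(1996, 2006, by = 5), 10000)
  expect_error(back_project(st, rt, totals), "missing incidence")
  expect_error(forward_project(proj_state(), proj_rates(), totals, 2013),
               "multiple of the step")
  expect_error(forward_project(proj_state(), proj_rates(), totals, 2001),
               "exceed")
})

test_that("prevalence series matches arithmetic and monotonicity", {
  g <- age_grid(60, 70)
  st <- population_state(2006, g, c(100, 50, 0), c(20, 10, 0))
  expect_equal(prevalence_series(list(st))$prevalence, 30 / 150)
  st2 <- population_state(2011, g, c(100, 50, 0), c(40, 20, 0))
  ps <- prevalence_series(list(st, st2))
  expect_true(diff(ps$prevalence) > 0)
  all_dm <- population_state(2006, g, c(100, 50, 10), c(100, 50, 10))
  expect_equal(prevalence_series(list(all_dm))$prevalence, 1)
})

test_that("doubling time follows the linear-growth arithmetic", {
  g <- age_grid(60, 70)
  mk <- function(year, nd) population_state(year, g, rep(1e4, 3),
                                            c(nd, 0, 0))
  # slope 10/year, size 100 at the reference year
  expect_equal(doubling_time(list(mk(1996, 0), mk(2006, 100)),
                             reference_year = 2006)$raw_years, 10)
  # states 80, 100, 120: mean slope 4/year, doubling 120/4 = 30 years
  dt <- doubling_time(list(mk(1996, 80), mk(2001, 100), mk(2006, 120)),
                      reference_year = 2006)
  expect_equal(dt$raw_years, 30)
  expect_equal(dt$doubling_years, 30)
  # invariant to uniform rescaling of all counts
  dt_scaled <- doubling_time(list(mk(1996, 8), mk(2001, 10), mk(2006, 12)),
                             reference_year = 2006)
  expect_equal(dt_scaled$raw_years, 30)
  # shrinking population: signalled, not an exception
  shrink <- doubling_time(list(mk(1996, 120), mk(2006, 100)),
                          reference_year = 2006)
  expect_true(shrink$no_doubling)
  expect_true(is.na(shrink$doubling_years))
})

test_that("scenario sweep is consistent with single projections and ordered", {
  rt <- proj_rates()
  st <- proj_state(year = 2006)
  totals <- flat_totals(grid30, seq(2006, 2026, by = 5), 10000)
  sw1 <- scenario_sweep(st, rt, totals, 2026, multipliers = 1)
  direct <- forward_project(st, rt, totals, 2026)
  last <- direct[[length(direct)]]
  expect_equal(sw1$size_at_horizon,
               sum(last$n_diabetic[last$age_start >= 60]))

  sw <- scenario_sweep(st, rt, totals, 2026,
                       multipliers = c(0.25, 0.5, 0.75, 1, 1.25, 1.5, 1.75))
  expect_true(all(diff(sw$size_at_horizon) > 0))
  expect_true(all(diff(sw$doubling_time_raw) <= 0))
  expect_true(all(diff(sw$doubling_time) <= 0))
  expect_error(scenario_sweep(st, rt, totals, 2026, multipliers = c(1, -1)),
               "positive")
})

test_that("back-projection recovers the baseline of a microsimulated step", {
  # 100,000 simulated persons aged 60+ in five groups: large enough that
  # 2% per group is over three binomial standard errors
  g <- age_grid(60, 80)
  st <- proj_state(grid = g, year = 2006, per_group = 2e4, prev = 0.21)
  rt <- proj_rates(grid = g)
  totals <- flat_totals(g, c(2006, 2011), 2e4)
  sim <- simulate_projection_step(st, rt, totals, seed = 61)
  rec <- back_project(sim, rt, totals)
  rel <- abs(rec$n_diabetic - st$n_diabetic) / st$n_diabetic
  expect_lt(max(rel), 0.02)
  # the closure without the recorded open split stays within tolerance too
  attr(sim, "open_inflow") <- NULL
  rec2 <- back_project(sim, rt, totals)
  rel2 <- abs(rec2$n_diabetic - st$n_diabetic) / st$n_diabetic
  expect_lt(max(rel2), 0.02)
})
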
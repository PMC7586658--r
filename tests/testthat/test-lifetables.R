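gompertz60 <- function(a) 0.01 * exp(0.09 * (a - 60))

test_that("a constant hazard gives life expectancy 1/m", {
  # single open-ended group: nLx = lx/mx closes the table exactly
  g1 <- age_grid(60, 65)     # one closed + open group
  lt1 <- life_table(c(0.05, 0.05), g1)
  expect_equal(life_expectancy(lt1, 60), 20)
  # the identity survives any number of constant-hazard 5-year groups
  lt <- life_table(rep(0.05, 8), grid60)
  expect_equal(life_expectancy(lt, 60), 20)
  expect_equal(life_expectancy(lt, 80), 20)
})

test_that("a two-group toy table matches the hand computation", {
  g <- age_grid(60, 65)
  lt <- life_table(c(0.1, 0.2), g)
  q1 <- 0.5 / 1.25                       # 5*0.1 / (1 + 2.5*0.1)
  l2 <- 1e5 * (1 - q1)
  nL1 <- 5 * l2 + 2.5 * 1e5 * q1
  nL2 <- l2 / 0.2
  expect_equal(lt$qx, c(q1, 1))
  expect_equal(lt$lx, c(1e5, l2))
  expect_equal(lt$nLx, c(nL1, nL2))
  expect_equal(life_expectancy(lt, 60), (nL1 + nL2) / 1e5)
  expect_equal(lt$Tx, rev(cumsum(rev(lt$nLx))))
})

test_that("table structure invariants hold on a realistic schedule", {
  mx <- gompertz60(grid60$age_start + 2.5)
  lt <- life_table(mx, grid60)
  expect_true(all(diff(lt$lx) <= 0))
  expect_equal(lt$lx[1], 1e5)
  expect_true(all(lt$qx >= 0 & lt$qx <= 1))
  expect_equal(lt$qx[8], 1)
  expect_equal(lt$ex, lt$Tx / lt$lx)
  expect_error(life_table(c(mx[-8], 0), grid60), "open-group")
})

test_that("abridged e60 agrees with single-year survival integration", {
  for (B in c(0.07, 0.09, 0.11)) {
    mu <- function(a) 0.01 * exp(B * (a - 60))
    mx <- group_mx_from_hazard(mu, grid60)
    e_abr <- life_expectancy(life_table(mx, grid60), 60)
    e_ref <- e_numeric(mu, 60)
    expect_lt(abs(e_abr - e_ref), 0.05)
  }
})

test_that("scenario schedules implement deletion and re-insertion", {
  mx <- gompertz60(grid60$age_start + 2.5)
  f <- rep(0.1, 8)
  all_ <- scenario_schedule(mx, f, 0, "all_cause")
  expect_equal(all_$mx, mx)
  del <- scenario_schedule(mx, f, 0, "delete_dm2")
  expect_equal(del$mx, 0.9 * mx)
  # re-inserting exactly the deleted mortality restores the schedule
  re <- scenario_schedule(mx, f, 0.1 * mx, "delete_dm2_add_model")
  expect_equal(re$mx, mx)
  # f = 0, h = 0: all three coincide
  expect_equal(scenario_schedule(mx, 0, 0, "delete_dm2")$mx, mx)
  expect_equal(scenario_schedule(mx, 0, 0, "delete_dm2_add_model")$mx, mx)
  expect_error(scenario_schedule(mx, rep(1, 8), 0, "delete_dm2"),
               "\\[0, 1\\)")
})

test_that("cause deletion never lowers life expectancy", {
  set.seed(53)
  for (i in 1:20) {
    mx <- exp(log(gompertz60(grid60$age_start + 2.5)) + rnorm(8, 0, 0.2))
    f <- runif(8, 0, 0.3)
    e_all <- life_expectancy(life_table(mx, grid60), 60)
    e_del <- life_expectancy(life_table(mx * (1 - f), grid60), 60)
    expect_gte(e_del, e_all)
  }
})

test_that("scenario ordering matches excess model hazard", {
  # when the model-based diabetes hazard exceeds the registry-deleted
  # mortality: e60(reinsert) < e60(all-cause) < e60(delete)
  mx <- gompertz60(grid60$age_start + 2.5)
  f <- rep(0.05, 8)
  h <- 0.08 * mx                       # h > f * mx
  e <- function(s) life_expectancy(life_table(s$mx, grid60), 60)
  e1 <- e(scenario_schedule(mx, f, h, "all_cause"))
  e2 <- e(scenario_schedule(mx, f, h, "delete_dm2"))
  e3 <- e(scenario_schedule(mx, f, h, "delete_dm2_add_model"))
  expect_lt(e3, e1)
  expect_lt(e1, e2)
})

test_that("years of life lost reproduces the published-style arithmetic", {
  # constant-hazard tables hit any target e60 exactly at m = 1/e60
  tab <- function(e) life_table(rep(1 / e, 8), grid60)
  expect_equal(yll_at_60(tab(24.33), tab(24.33)), 0)
  yll_2025 <- yll_at_60(tab(24.33), tab(23.73))
  expect_equal(yll_2025, 24.33 - 23.73)
  expect_lt(abs(yll_2025 - 0.602), 0.01)
  yll_2035 <- yll_at_60(tab(24.97), tab(24.37))
  expect_lt(abs(yll_2035 - 0.597), 0.01)
  # a negative value is returned (flagged), not clipped
  expect_message(neg <- yll_at_60(tab(24), tab(25)), "negative")
  expect_equal(neg, -1)
  expect_error(yll_at_60(tab(24), life_table(rep(1 / 24, 3),
                                             age_grid(60, 70))),
               "grids")
})

lc_fit_60 <- function(drift = -0.3, sigma_kt = 0.3, sigma_eps = 0.005,
                      seed = 59) {
  sp <- surface_spec(grid = grid60,
                     true_ax = log(c(0.01, 0.016, 0.025, 0.04, 0.065,
                                     0.105, 0.17, 0.28)),
                     true_bx = rep(1 / 8, 8), true_drift = drift,
                     sigma_kt = sigma_kt, sigma_eps = sigma_eps,
                     diabetes_fraction_by_age = rep(0.05, 8), seed = seed)
  lc(generate_mortality_surface(sp))
}

test_that("forecast-based YLL intervals behave and degenerate correctly", {
  f <- rep(0.05, 8)
  fit <- lc_fit_60()
  fc <- lc_forecast(fit, horizon = 15, n_sims = 400, seed = 2)
  h <- 0.08 * exp(fit$ax)
  ci <- yll_confidence_interval(fc, f, h, year = 2025)
  expect_true(ci$lower <= ci$median && ci$median <= ci$upper)
  expect_gt(ci$median, 0)
  expect_equal(length(ci$samples), 400)
  # too few trajectories refused
  fc_small <- lc_forecast(fit, horizon = 15, n_sims = 50, seed = 2)
  expect_error(yll_confidence_interval(fc_small, f, h, 2025),
               "at least 100")
  # no innovation noise: a degenerate interval
  fit0 <- lc_fit_60(sigma_kt = 0, sigma_eps = 0)
  fc0 <- lc_forecast(fit0, horizon = 15, n_sims = 150,
                     drift_uncertainty = FALSE, seed = 2)
  ci0 <- yll_confidence_interval(fc0, f, h, 2025)
  expect_equal(ci0$lower, ci0$upper, tolerance = 1e-10)
  expect_equal(ci0$lower, ci0$median, tolerance = 1e-10)
})

test_that("the e60 scenario table mirrors the published layout", {
  fit <- lc_fit_60()
  fc <- lc_forecast(fit, horizon = 15, n_sims = 300, seed = 9)
  f <- rep(0.05, 8)
  h <- 0.08 * exp(fit$ax)
  tab <- e60_scenario_table(fc, f, h, years = c(2020, 2025))
  expect_equal(nrow(tab), 8L)
  expect_setequal(unique(tab$quantity),
                  c("e60_all_cause", "e60_delete_dm2",
                    "e60_delete_add_model", "yll"))
  expect_true(all(tab$lower <= tab$estimate & tab$estimate <= tab$upper))
  expect_match(tab$cell[1], "^\\d+\\.\\d{2} \\(\\d+\\.\\d{2}-\\d+\\.\\d{2}\\)$")
  # within each year the scenario ordering holds for the estimates
  for (yr in c(2020, 2025)) {
    e <- tab[tab$year == yr, ]
    est <- stats::setNames(e$estimate, e$quantity)
    expect_lt(est["e60_delete_add_model"], est["e60_all_cause"])
    expect_lt(est["e60_all_cause"], est["e60_delete_dm2"])
    expect_equal(unname(est["yll"]),
                 unname(est["e60_all_cause"] - est["e60_delete_add_model"]),
                 tolerance = 0.15)   # medians are not exactly additive
  }
})
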
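#' Default pipeline configuration
#'
#' Assembles the configuration for [run_pipeline()]: one list holding the
#' seed, synthetic-data parameters, projection window, scenario multipliers,
#' forecast settings and the switches covering the method's documented
#' ambiguities (`formula_qx`, separation factors).
#'
#' @param seed master integer seed; all stage seeds derive from it.
#' @param n_subjects synthetic cohort size.
#' @param baseline_year baseline of the projection (default 2005).
#' @param horizon_year last projected year (default 2025).
#' @param fit_years year window of the mortality fit (default 1980-2010).
#' @param forecast_horizon years of mortality forecast (default 25, ending
#'   2035 from a 2010 endpoint).
#' @param n_sims forecast trajectories.
#' @param level interval coverage.
#' @param multipliers incidence scenario multipliers.
#' @param formula_qx denominator reading of the projection formula.
#' @param step projection step (years).
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 1L,
                       n_subjects = 2827,
                       baseline_year = 2005,
                       horizon_year = 2025,
                       fit_years = c(1980, 2010),
                       forecast_horizon = 25,
                       n_sims = 1000,
                       level = 0.95,
                       multipliers = c(0.25, 0.5, 0.75, 1, 1.25, 1.5, 1.75),
                       formula_qx = "diabetic",
                       step = 5) {
  cfg <- list(seed = seed, n_subjects = n_subjects,
              baseline_year = baseline_year, horizon_year = horizon_year,
              fit_years = fit_years, forecast_horizon = forecast_horizon,
              n_sims = n_sims, level = level, multipliers = multipliers,
              formula_qx = formula_qx, step = step)
  if (cfg$horizon_year <= cfg$baseline_year)
    stop("horizon_year must exceed baseline_year")
  if (cfg$n_sims < 1) stop("n_sims must be >= 1")
  class(cfg) <- "run_config"
  cfg
}

#' @rdname run_config
#' @param path YAML file with (a subset of) the configuration fields.
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

# Synthetic national population totals on the 30+ grid: a geometrically
# thinning age profile growing at a constant annual rate.
make_totals_series <- function(grid, years, base_year, base_total = 2.6e6,
                               age_slope = 0.05, growth = 0.015) {
  prof <- exp(-age_slope * (grid$age_start - grid$age_start[1]))
  prof <- prof / sum(prof)
  do.call(rbind, lapply(years, function(y)
    data.frame(year = y, age_start = grid$age_start,
               n_total = base_total * (1 + growth)^(y - base_year) * prof)))
}

# National-style fallback rates for ages 30-59, where the cohort carries no
# information: prevalence and incidence ramps, and all-cause mortality from
# the historical surface standing in for the diabetic death rate.
adult_fallback_rates <- function(grid, surface) {
  ages <- grid$age_start
  prev <- ifelse(ages < 60, 0.02 + 0.0045 * (ages - 30), NA_real_)
  inc <- ifelse(ages < 60, 0.003 + 0.00022 * (ages - 30), NA_real_)
  j <- ncol(surface$m)
  m_all <- surface$m[match(ages, surface$grid$age_start), j]
  m <- ifelse(ages < 60, m_all, NA_real_)
  rate_table(grid, prevalence = prev, incidence = inc, m_diabetic = m,
             q_diabetic = mx_to_qx(m, grid$age_width), source = "national")
}

#' Run the full projection pipeline
#'
#' Executes every stage end to end on synthetic data: generate (cohort,
#' utilization, mortality surface, population totals); estimate rates;
#' back-project the baseline diabetic population two steps and compute the
#' doubling time; sweep the incidence scenarios forward to the horizon;
#' fit the two-part cost models and project cost shares; fit and forecast
#' mortality for the all-cause and diabetes-deleted streams; and build the
#' life-table scenario table with years of life lost at 60. All tables are
#' written as CSV under `outdir` together with a YAML manifest (config,
#' seeds, file list, row counts).
#'
#' @param config a [run_config()] (or a YAML path readable by
#'   [read_run_config()]).
#' @param outdir output directory (created if missing); `NULL` skips
#'   writing.
#' @return Invisibly, a list with all intermediate objects: `cohort`,
#'   `rates`, `back_states`, `doubling`, `sweep`, `costs`, `fits`,
#'   `forecasts`, `e60_table`, `e0`, `manifest`.
#' @export
run_pipeline <- function(config = run_config(), outdir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  seed <- config$seed
  step <- config$step

  ## --- generate -----------------------------------------------------------
  cohort <- generate_cohort(cohort_spec(n_subjects = config$n_subjects,
                                        baseline_year = config$baseline_year,
                                        seed = child_seed(seed, "cohort")))
  cohort <- generate_utilization(cohort, service = "hospitalization",
                                 seed = child_seed(seed, "hosp"))
  cohort <- generate_utilization(cohort, service = "outpatient",
                                 seed = child_seed(seed, "outp"))
  surface <- generate_mortality_surface(surface_spec(
    years = config$fit_years[1]:config$fit_years[2],
    seed = child_seed(seed, "surface")))
  grid30 <- age_grid(30, 95)
  years_needed <- seq(config$baseline_year - 2 * step,
                      config$horizon_year, by = step)
  totals <- make_totals_series(grid30, years_needed, config$baseline_year)

  ## --- rates --------------------------------------------------------------
  grid60 <- age_grid(60, 95)
  prev60 <- estimate_prevalence(cohort, grid60)
  inc60 <- estimate_incidence(cohort, grid60)
  mort60 <- estimate_diabetic_mortality(cohort, grid60)
  est60 <- rate_table(grid60,
                      prevalence = prev60$prevalence,
                      incidence = inc60$incidence,
                      m_diabetic = mort60$m_diabetic,
                      q_diabetic = mort60$q_diabetic,
                      source = "cohort-estimated")
  full <- rate_table(grid30)
  m60 <- match(grid60$age_start, grid30$age_start)
  for (col in c("prevalence", "incidence", "m_diabetic", "q_diabetic"))
    full[[col]][m60] <- est60[[col]]
  full$source[m60] <- "cohort-estimated"
  rates <- fill_rate_table(full, adult_fallback_rates(grid30, surface))
  # any elderly group left empty by the cohort is completed from the
  # neighbouring estimate (never zero-filled)
  for (col in c("prevalence", "incidence", "m_diabetic", "q_diabetic")) {
    v <- rates[[col]]
    if (anyNA(v)) {
      for (i in which(is.na(v)))
        v[i] <- v[max(which(!is.na(v[seq_len(i)])))]
      rates[[col]] <- v
    }
  }

  ## --- projection ---------------------------------------------------------
  base_tot <- totals_at(totals, config$baseline_year, grid30)
  base_state <- population_state(config$baseline_year, grid30, base_tot,
                                 base_tot * rates$prevalence)
  st2001 <- back_project(base_state, rates, totals, step = step,
                         formula_qx = config$formula_qx)
  st1996 <- back_project(st2001, rates, totals, step = step,
                         formula_qx = config$formula_qx)
  back_states <- list(st1996, st2001, base_state)
  doubling <- doubling_time(back_states,
                            reference_year = config$baseline_year)
  sweep <- scenario_sweep(base_state, rates, totals, config$horizon_year,
                          multipliers = config$multipliers, step = step,
                          formula_qx = config$formula_qx)
  i1 <- match(1, config$multipliers)
  base_run <- if (!is.na(i1)) attr(sweep, "states")[[i1]] else
    forward_project(base_state, rates, totals, config$horizon_year,
                    step = step, formula_qx = config$formula_qx)
  series <- prevalence_series(base_run)
  series$diabetic_60plus <- vapply(base_run, function(st)
    sum(st$n_diabetic[st$age_start >= 60]), numeric(1))

  ## --- costs --------------------------------------------------------------
  unit <- unit_cost_table()
  costs <- do.call(rbind, lapply(c("hospitalization", "outpatient"),
    function(svc) {
      fit <- two_part(cohort, svc)
      pc <- expected_cost_per_capita(fit, unit)
      project_costs(base_run, pc, svc)
    }))

  ## --- mortality forecast -------------------------------------------------
  truth <- attr(surface, "truth")
  dm2_fraction <- truth$diabetes_fraction_by_age
  fit_all <- lc(surface)
  surface_nd <- cause_deleted_surface(surface, dm2_fraction)
  fit_nd <- lc(surface_nd)
  fc_all <- lc_forecast(fit_all, horizon = config$forecast_horizon,
                        n_sims = config$n_sims, level = config$level,
                        seed = child_seed(seed, "fc_all"))
  fc_nd <- lc_forecast(fit_nd, horizon = config$forecast_horizon,
                       n_sims = config$n_sims, level = config$level,
                       seed = child_seed(seed, "fc_nd"))

  ## --- life tables --------------------------------------------------------
  ages_s <- surface$grid$age_start
  csh <- cause_specific_hazards(cohort, grid60)
  h_model <- ifelse(ages_s < 30, 0,
             ifelse(ages_s < 60,
                    dm2_fraction * surface$m[, ncol(surface$m)], 0))
  m_h <- match(grid60$age_start, ages_s)
  h60 <- csh$hazard_diabetes
  h60[is.na(h60)] <- 0
  h_model[m_h] <- h60
  yr_end <- max(fc_all$years)
  nax0 <- ifelse(is.finite(surface$grid$age_width),
                 surface$grid$age_width / 2, NA_real_)
  nax0[1] <- if (ages_s[1] == 0) 1.5 else nax0[1]
  e0 <- list(
    all_cause = life_expectancy(
      life_table(forecast_schedule(fc_all, yr_end), surface$grid, nax0), 0),
    delete_dm2 = life_expectancy(
      life_table(forecast_schedule(fc_nd, yr_end), surface$grid, nax0), 0)
  )
  e60_years <- unique(c(config$horizon_year, yr_end))
  e60_table <- e60_scenario_table(fc_all, dm2_fraction, h_model,
                                  years = e60_years, level = config$level)

  ## --- outputs ------------------------------------------------------------
  manifest <- list(
    package_version = as.character(utils::packageVersion("dmburden")),
    config = unclass(config),
    stages = list(
      cohort_rows = nrow(cohort),
      rate_groups = nrow(rates),
      projected_years = vapply(base_run, state_year, numeric(1)),
      forecast_years = range(fc_all$years)
    )
  )
  res <- list(cohort = cohort, rates = rates, back_states = back_states,
              doubling = doubling, sweep = sweep, series = series,
              costs = costs, fits = list(all = fit_all, nondm = fit_nd),
              forecasts = list(all = fc_all, nondm = fc_nd),
              e60_table = e60_table, e0 = e0, manifest = manifest)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(outdir, f)
    write_cohort_csv(cohort, p("cohort.csv"))
    write_rate_table_csv(rates, p("rates.csv"))
    utils::write.csv(sweep, p("table2_scenarios.csv"), row.names = FALSE)
    utils::write.csv(series, p("fig2_series.csv"), row.names = FALSE)
    utils::write.csv(costs, p("fig3_costs.csv"), row.names = FALSE)
    utils::write.csv(e60_table, p("table3_e60.csv"), row.names = FALSE)
    write_surface_csv(surface, p("surface.csv"))
    for (w in c("median", "lower", "upper")) {
      fs <- mortality_surface(fc_all[[w]], surface$grid, fc_all$years)
      write_surface_csv(fs, p(paste0("forecast_", w, ".csv")))
    }
    yaml::write_yaml(manifest, p("manifest.yml"))
    manifest$config_md5 <- unname(tools::md5sum(p("manifest.yml")))
    res$manifest <- manifest
  }
  invisible(res)
}
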
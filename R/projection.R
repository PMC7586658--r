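#' Population state by age group
#'
#' Diabetic / non-diabetic population counts by age group at one calendar
#' year: the object the projection recurrence transforms. Fractional persons
#' are kept throughout; rounding happens only at report time.
#'
#' @param year calendar year.
#' @param grid an [age_grid()].
#' @param n_total total population per age group (>= 0).
#' @param n_diabetic diabetic population per age group (>= 0, elementwise
#'   at most `n_total`).
#' @return A data frame of class `population_state` with columns `age_start`,
#'   `age_width`, `n_total`, `n_diabetic`, `n_nondiabetic`, and the year in
#'   attribute `"year"`.
#' @export
population_state <- function(year, grid, n_total, n_diabetic) {
  stopifnot_grid(grid)
  n_total <- as.numeric(n_total); n_diabetic <- as.numeric(n_diabetic)
  if (length(n_total) != nrow(grid) || length(n_diabetic) != nrow(grid))
    stop("counts must have one value per age group")
  if (any(n_total < 0) || any(n_diabetic < -1e-9))
    stop("counts must be >= 0")
  if (any(n_diabetic > n_total + 1e-6))
    stop("diabetic count exceeds total")
  st <- data.frame(
    age_start = grid$age_start, age_width = grid$age_width,
    n_total = n_total, n_diabetic = pmax(0, n_diabetic),
    n_nondiabetic = pmax(0, n_total - n_diabetic)
  )
  attr(st, "year") <- year
  class(st) <- c("population_state", "data.frame")
  st
}

#' @export
print.population_state <- function(x, ...) {
  cat("Population state, year", attr(x, "year"), "-",
      format(round(sum(x$n_total))), "persons,",
      format(round(sum(x$n_diabetic))), "diabetic\n")
  print.data.frame(x, ...)
  invisible(x)
}

state_year <- function(state) attr(state, "year")

# Totals lookup: `totals` is a long data frame (year, age_start, n_total).
totals_at <- function(totals, year, grid) {
  sel <- totals[totals$year == year, ]
  if (nrow(sel) == 0L) stop("no total-population counts for year ", year)
  m <- match(grid$age_start, sel$age_start)
  if (any(is.na(m))) stop("total-population counts missing age groups for ",
                          year)
  sel$n_total[m]
}

# Interval quantities entering the recurrence: the t-year cumulative
# diagnosis risk (from the annual incidence rate, scaled by the scenario
# multiplier) and the interval death probability of the diabetic population.
interval_inputs <- function(rates, step, multiplier = 1,
                            formula_qx = c("diabetic", "allcause"),
                            m_allcause = NULL) {
  formula_qx <- match.arg(formula_qx)
  if (any(is.na(rates$incidence)) || any(is.na(rates$m_diabetic)))
    stop("rate table has missing incidence or diabetic mortality; ",
         "fill it from a national table first")
  td <- 1 - exp(-step * multiplier * rates$incidence)
  m <- if (formula_qx == "diabetic") rates$m_diabetic else {
    if (is.null(m_allcause))
      stop("formula_qx = 'allcause' requires m_allcause")
    m_allcause
  }
  qx <- mx_to_qx(m, ifelse(is.finite(rates$age_width),
                           rates$age_width, step))
  list(td = td, qx = qx)
}

#' Back-project the diabetic population one step
#'
#' Applies the projection recurrence in reverse: the diabetic count of the
#' cohort aged `x` at year `Y - t` is recovered from its descendants aged
#' `x + t` at year `Y` via
#' \deqn{N_x^d = \frac{N_{x+t}^d - N_x \, {}_td_x}{1 - {}_td_x \, {}_tq_x},}
#' where \eqn{{}_td_x} is the t-year cumulative diagnosis risk and
#' \eqn{{}_tq_x} the interval death probability of the diabetic population
#' (a switch allows the all-cause reading of the denominator). Non-diabetic
#' counts are the complement against the supplied total-population series.
#'
#' The open terminal group mixes two ancestor cohorts (the penultimate group
#' and the open group's own survivors). When the state carries the
#' `"open_inflow"` attribute written by [forward_project()] the split is
#' inverted exactly; otherwise it is closed by assuming the open group's
#' prevalence at `Y - t` equals the penultimate group's, which is exact for
#' age-flat old-age prevalence and documented as an approximation otherwise.
#'
#' @param state a [population_state()] at year `Y`.
#' @param rates a complete [rate_table()] on the state's grid (annual
#'   incidence; diabetic central death rates).
#' @param totals total-population series: data frame `(year, age_start,
#'   n_total)` covering year `Y - t`.
#' @param step projection step in years (default 5, the grid width).
#' @param multiplier incidence scenario multiplier (> 0).
#' @param formula_qx `"diabetic"` (default) or `"allcause"` denominator.
#' @param m_allcause all-cause central death rates, needed only for the
#'   all-cause denominator reading.
#' @return A [population_state()] at year `Y - t`. Negative numerators are
#'   floored at zero with a warning naming the offending group.
#' @export
back_project <- function(state, rates, totals, step = 5, multiplier = 1,
                         formula_qx = c("diabetic", "allcause"),
                         m_allcause = NULL) {
  formula_qx <- match.arg(formula_qx)
  grid <- state[, c("age_start", "age_width")]
  class(grid) <- c("age_grid", "data.frame")
  k <- nrow(state)
  iv <- interval_inputs(rates, step, multiplier, formula_qx, m_allcause)
  denom <- 1 - iv$td * iv$qx
  if (any(denom <= 0))
    stop("non-positive denominator in age group ",
         paste(age_group_labels(grid)[denom <= 0], collapse = ", "))
  year_prev <- state_year(state) - step
  n_prev <- totals_at(totals, year_prev, grid)
  nd_prev <- rep(NA_real_, k)

  # closed cohorts: group g at Y - t descends into group g + 1 at Y
  for (g in seq_len(k - 2L)) {
    nd_prev[g] <- (state$n_diabetic[g + 1L] - n_prev[g] * iv$td[g]) /
      denom[g]
  }
  # terminal pair: penultimate group and open-group survivors both land in
  # the open group at Y
  pen <- k - 1L
  inflow <- attr(state, "open_inflow")
  if (!is.null(inflow)) {
    nd_prev[pen] <- (inflow - n_prev[pen] * iv$td[pen]) / denom[pen]
    nd_prev[k] <- (state$n_diabetic[k] - inflow - n_prev[k] * iv$td[k]) /
      denom[k]
  } else {
    # prevalence-matching closure: N_open^d = rho * N_pen^d at Y - t
    rho <- if (n_prev[pen] > 0) n_prev[k] / n_prev[pen] else 0
    # open(Y) = pen_cohort + open_cohort
    #         = nd_pen*denom[pen] + Npen*td + rho*nd_pen*denom[k] + Nopen*td
    coef <- denom[pen] + rho * denom[k]
    rhs <- state$n_diabetic[k] - n_prev[pen] * iv$td[pen] -
      n_prev[k] * iv$td[k]
    nd_prev[pen] <- rhs / coef
    nd_prev[k] <- rho * nd_prev[pen]
  }
  neg <- nd_prev < 0
  if (any(neg)) {
    warning("negative back-projected diabetic count floored at 0 in group ",
            paste(age_group_labels(grid)[neg], collapse = ", "))
    nd_prev[neg] <- 0
  }
  nd_prev <- pmin(nd_prev, n_prev)
  population_state(year_prev, grid, n_prev, nd_prev)
}

#' Forward-project the diabetic population
#'
#' Inverts the back-projection recurrence cohort-wise: survivors of each
#' diabetic cohort move up one age group while incident cases accrue in
#' proportion to the total population,
#' \deqn{N_{x+t}^d = N_x^d (1 - {}_td_x \, {}_tq_x) + N_x \, {}_td_x.}
#' The open terminal group accumulates the outflow of the penultimate group
#' plus its own survivors (no one ages out). Entrants at the youngest group
#' are taken from the supplied total-population series at the entrant
#' prevalence. Migration is null and rates are constant over time by
#' assumption.
#'
#' @param state baseline [population_state()].
#' @param rates,totals,step,multiplier,formula_qx,m_allcause as in
#'   [back_project()]; `totals` must cover every projected year.
#' @param horizon_year final year; `horizon_year - year(state)` must be a
#'   positive multiple of `step`.
#' @param entrant_prevalence diabetes prevalence applied to the youngest
#'   group of each new period (default: the baseline state's youngest-group
#'   prevalence).
#' @return A list of [population_state()]s from the baseline to the horizon
#'   (the baseline first). Each projected state carries the
#'   `"open_inflow"` attribute making [back_project()] its exact inverse.
#' @export
forward_project <- function(state, rates, totals, horizon_year, step = 5,
                            multiplier = 1,
                            formula_qx = c("diabetic", "allcause"),
                            m_allcause = NULL,
                            entrant_prevalence = NULL) {
  formula_qx <- match.arg(formula_qx)
  y0 <- state_year(state)
  if (horizon_year <= y0) stop("horizon_year must exceed the state's year")
  if ((horizon_year - y0) %% step != 0)
    stop("horizon_year - baseline year must be a multiple of the step")
  grid <- state[, c("age_start", "age_width")]
  class(grid) <- c("age_grid", "data.frame")
  k <- nrow(state)
  iv <- interval_inputs(rates, step, multiplier, formula_qx, m_allcause)
  surv <- 1 - iv$td * iv$qx
  if (is.null(entrant_prevalence)) {
    entrant_prevalence <- if (state$n_total[1] > 0)
      state$n_diabetic[1] / state$n_total[1] else 0
  }
  states <- vector("list", (horizon_year - y0) / step + 1L)
  states[[1L]] <- state
  cur <- state
  for (s in seq_len(length(states) - 1L)) {
    yr <- y0 + s * step
    n_new <- totals_at(totals, yr, grid)
    nd_new <- rep(NA_real_, k)
    nd_new[1L] <- entrant_prevalence * n_new[1L]
    for (g in 2L:(k - 1L)) {
      nd_new[g] <- cur$n_diabetic[g - 1L] * surv[g - 1L] +
        cur$n_total[g - 1L] * iv$td[g - 1L]
    }
    pen <- k - 1L
    inflow <- cur$n_diabetic[pen] * surv[pen] + cur$n_total[pen] * iv$td[pen]
    own <- cur$n_diabetic[k] * surv[k] + cur$n_total[k] * iv$td[k]
    nd_new[k] <- inflow + own
    nd_new <- pmin(nd_new, n_new)
    st <- population_state(yr, grid, n_new, nd_new)
    attr(st, "open_inflow") <- inflow
    states[[s + 1L]] <- st
    cur <- st
  }
  states
}

#' Elderly diabetes prevalence along a projection
#'
#' @param states list of [population_state()]s.
#' @param min_age lower age bound of the prevalence denominator (default 60).
#' @return Data frame `(year, prevalence)`: summed diabetic counts over
#'   summed totals for groups starting at `min_age` or above.
#' @export
prevalence_series <- function(states, min_age = 60) {
  out <- lapply(states, function(st) {
    sel <- st$age_start >= min_age
    den <- sum(st$n_total[sel])
    if (den <= 0) stop("zero elderly population in year ", state_year(st))
    data.frame(year = state_year(st),
               prevalence = sum(st$n_diabetic[sel]) / den)
  })
  do.call(rbind, out)
}

#' Doubling time of the diabetic elderly population
#'
#' Under the constant linear (arithmetic) growth assumption: the annualized
#' growth `r` is the mean of the per-period slopes of the diabetic 60+
#' population, and the doubling time is the reference-year population
#' divided by `r` — the years needed to add that many diabetic persons
#' again. Reported rounded to the nearest half-year alongside the raw value.
#'
#' @param states list of at least two [population_state()]s (any order;
#'   sorted by year internally).
#' @param reference_year year whose population is to double (default: the
#'   latest state).
#' @param min_age lower age bound (default 60).
#' @return List with `doubling_years` (half-year rounding), `raw_years`,
#'   `growth_per_year`, and `reference_size`. When the mean slope is not
#'   positive, `doubling_years` and `raw_years` are `NA` and `no_doubling`
#'   is `TRUE`.
#' @export
doubling_time <- function(states, reference_year = NULL, min_age = 60) {
  if (length(states) < 2L) stop("need at least two states")
  yrs <- vapply(states, state_year, numeric(1))
  o <- order(yrs)
  yrs <- yrs[o]; states <- states[o]
  size <- vapply(states, function(st)
    sum(st$n_diabetic[st$age_start >= min_age]), numeric(1))
  reference_year <- reference_year %||% yrs[length(yrs)]
  i <- match(reference_year, yrs)
  if (is.na(i)) stop("reference_year is not among the states")
  if (size[i] <= 0) stop("reference population is not positive")
  slopes <- diff(size) / diff(yrs)
  r <- mean(slopes)
  if (r <= 0) {
    return(list(doubling_years = NA_real_, raw_years = NA_real_,
                growth_per_year = r, reference_size = size[i],
                no_doubling = TRUE))
  }
  raw <- size[i] / r
  list(doubling_years = round(raw * 2) / 2, raw_years = raw,
       growth_per_year = r, reference_size = size[i], no_doubling = FALSE)
}

#' Incidence scenario sweep
#'
#' Runs one forward projection per incidence multiplier under otherwise
#' identical assumptions and tabulates, per scenario, the diabetic elderly
#' population and prevalence at the horizon and the doubling time computed
#' from the projected series.
#'
#' @inheritParams forward_project
#' @param multipliers positive multipliers applied to the annual incidence
#'   rates (canonically `c(0.25, 0.5, 0.75, 1, 1.25, 1.5, 1.75)`).
#' @param min_age lower age bound for the elderly summaries (default 60).
#' @return Data frame with one row per multiplier: `multiplier`,
#'   `size_at_horizon`, `prevalence_at_horizon`, `doubling_time`,
#'   `doubling_time_raw`. The full state lists are in attribute `"states"`.
#' @export
scenario_sweep <- function(state, rates, totals, horizon_year,
                           multipliers = c(0.25, 0.5, 0.75, 1,
                                           1.25, 1.5, 1.75),
                           step = 5, min_age = 60, ...) {
  if (any(multipliers <= 0)) stop("multipliers must be positive")
  runs <- lapply(multipliers, function(m)
    forward_project(state, rates, totals, horizon_year, step = step,
                    multiplier = m, ...))
  rows <- Map(function(m, states) {
    last <- states[[length(states)]]
    sel <- last$age_start >= min_age
    dt <- doubling_time(states, reference_year = state_year(state),
                        min_age = min_age)
    data.frame(
      multiplier = m,
      size_at_horizon = sum(last$n_diabetic[sel]),
      prevalence_at_horizon = sum(last$n_diabetic[sel]) /
        sum(last$n_total[sel]),
      doubling_time = dt$doubling_years,
      doubling_time_raw = dt$raw_years
    )
  }, multipliers, runs)
  out <- do.call(rbind, rows)
  attr(out, "states") <- runs
  out
}

#' Individual-level realization of one projection step
#'
#' Monte-Carlo oracle for the projection recurrence: every person alive at
#' the baseline independently generates a new-diagnosis event with the
#' interval risk \eqn{{}_td_x}, and every prevalent diabetic is removed with
#' the recurrence's attrition probability \eqn{{}_td_x \, {}_tq_x}, so the
#' expected diabetic count per descendant group equals the deterministic
#' recurrence exactly. Used to validate [back_project()] against independent
#' per-person bookkeeping (grid alignment, open-group handling, totals).
#'
#' @inheritParams forward_project
#' @param seed integer seed.
#' @return A [population_state()] at `year(state) + step` whose totals are
#'   taken from `totals` and whose diabetic counts are simulated.
#' @export
simulate_projection_step <- function(state, rates, totals, step = 5,
                                     multiplier = 1, seed = 1L,
                                     formula_qx = c("diabetic", "allcause"),
                                     m_allcause = NULL) {
  formula_qx <- match.arg(formula_qx)
  grid <- state[, c("age_start", "age_width")]
  class(grid) <- c("age_grid", "data.frame")
  k <- nrow(state)
  iv <- interval_inputs(rates, step, multiplier, formula_qx, m_allcause)
  with_seed(seed, {
    new_cases <- stats::rbinom(k, round(state$n_total), iv$td)
    deaths <- stats::rbinom(k, round(state$n_diabetic), iv$td * iv$qx)
    survivors <- round(state$n_diabetic) - deaths
    nd_dest <- numeric(k)
    # cohort g lands in g+1; penultimate and open both land in the open group
    for (g in seq_len(k - 1L))
      nd_dest[min(g + 1L, k)] <- nd_dest[min(g + 1L, k)] +
        survivors[g] + new_cases[g]
    nd_dest[k] <- nd_dest[k] + survivors[k] + new_cases[k]
    yr <- state_year(state) + step
    n_new <- totals_at(totals, yr, grid)
    nd_dest[1L] <- state$n_diabetic[1L] / max(state$n_total[1L], 1) *
      n_new[1L]
    st <- population_state(yr, grid, n_new, pmin(nd_dest, n_new))
    attr(st, "open_inflow") <- survivors[k - 1L] + new_cases[k - 1L]
    st
  })
}
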
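#' Age-group rate table
#'
#' The container tying together the age-specific quantities the projection
#' consumes: diabetes prevalence, annual diagnosis (incidence) rate among the
#' diabetes-free, the central death rate of the diabetic population, and the
#' corresponding interval probability of dying. Rows follow an [age_grid()].
#'
#' @param grid an [age_grid()].
#' @param prevalence,incidence,m_diabetic,q_diabetic per-group values
#'   (default `NA`; missing means "not yet estimated", never zero).
#' @param source provenance tag per group: `"cohort-estimated"`,
#'   `"national"` or `"assumed"`.
#' @return A data frame of class `rate_table` with columns `age_start`,
#'   `age_width`, `prevalence`, `incidence`, `m_diabetic`, `q_diabetic`,
#'   `source`.
#' @export
rate_table <- function(grid, prevalence = NA_real_, incidence = NA_real_,
                       m_diabetic = NA_real_, q_diabetic = NA_real_,
                       source = "assumed") {
  stopifnot_grid(grid)
  rt <- data.frame(
    age_start = grid$age_start, age_width = grid$age_width,
    prevalence = prevalence, incidence = incidence,
    m_diabetic = m_diabetic, q_diabetic = q_diabetic,
    source = source, stringsAsFactors = FALSE
  )
  validate_rate_table(rt)
  class(rt) <- c("rate_table", "data.frame")
  rt
}

validate_rate_table <- function(rt) {
  ok <- function(v) all(is.na(v) | (is.finite(v) & v >= 0))
  if (!ok(rt$incidence) || !ok(rt$m_diabetic))
    stop("rates must be finite and >= 0")
  p <- rt$prevalence
  if (!all(is.na(p) | (p >= 0 & p <= 1)))
    stop("prevalence must be in [0, 1]")
  q <- rt$q_diabetic
  if (!all(is.na(q) | (q >= 0 & q <= 1)))
    stop("q_diabetic must be in [0, 1]")
  invisible(rt)
}

#' Convert a central death rate to an interval death probability
#'
#' Uses the standard abridged life-table relation
#' \deqn{{}_nq_x = \frac{n \, m}{1 + (n - {}_na_x)\, m},}
#' where the separation factor \eqn{{}_na_x} is the average number of years
#' lived within the interval by those dying in it. The open-ended interval
#' (`n = Inf`) returns probability 1. Results are capped at 1.
#'
#' @param m annual central death rate(s), >= 0.
#' @param n interval width(s) in years; `Inf` for the open interval.
#' @param nax separation factor(s), in `(0, n]`; default `n/2`.
#' @return Death probabilities in `[0, 1]`, vectorized over the inputs.
#' @examples
#' mx_to_qx(0.02, 5, 2.5)   # 0.1/1.05
#' @export
mx_to_qx <- function(m, n, nax = n / 2) {
  if (any(m < 0, na.rm = TRUE)) stop("negative death rate")
  res <- cbind(m = m, n = n, nax = nax)   # recycles and checks lengths
  m <- res[, "m"]; n <- res[, "n"]; nax <- res[, "nax"]
  closed <- is.finite(n)
  if (any(closed & (nax <= 0 | nax > n), na.rm = TRUE))
    stop("nax must lie in (0, n] for closed intervals")
  q <- ifelse(closed, pmin(1, n * m / (1 + (n - nax) * m)), 1)
  q[is.na(m)] <- NA_real_
  unname(q)
}

# Weighted person-years of the interval [entry, exit) split across grid bins,
# plus weighted event tallies at event ages. Vectors are per subject; NA
# event_age means no event. Returns list(events, exposure) per bin.
person_years <- function(entry, exit, event_age, weight, grid) {
  keep <- !is.na(entry) & !is.na(exit) & exit > entry
  k <- nrow(grid)
  exposure <- numeric(k); events <- numeric(k)
  if (any(keep)) {
    e0 <- entry[keep]; e1 <- exit[keep]; w <- weight[keep]
    for (g in seq_len(k)) {
      lo <- grid$age_start[g]
      hi <- lo + grid$age_width[g]
      exposure[g] <- sum(w * pmax(0, pmin(e1, hi) - pmax(e0, lo)))
    }
  }
  ev <- !is.na(event_age)
  if (any(ev)) {
    idx <- age_group_index(event_age[ev], grid)
    t <- tapply(weight[ev], factor(idx, levels = seq_len(nrow(grid))), sum)
    events <- unname(ifelse(is.na(t), 0, as.numeric(t)))
  }
  list(events = events, exposure = exposure)
}

#' Estimate age-specific diabetes prevalence
#'
#' Weighted proportion of subjects reporting a diabetes diagnosis at
#' baseline, per age group. Groups without any weighted exposure are
#' returned as missing, never as zero.
#'
#' @param cohort a `synthetic_cohort` (or any data frame with columns
#'   `weight`, `age_at_baseline`, `diabetic_at_baseline`).
#' @param grid an [age_grid()].
#' @return A partial [rate_table()] with the `prevalence` column filled,
#'   tagged `"cohort-estimated"`.
#' @export
estimate_prevalence <- function(cohort, grid) {
  stopifnot_grid(grid)
  if (nrow(cohort) == 0L) stop("empty cohort")
  if (all(cohort$weight <= 0)) stop("all weights are zero")
  idx <- age_group_index(cohort$age_at_baseline, grid)
  f <- factor(idx, levels = seq_len(nrow(grid)))
  den <- tapply(cohort$weight, f, sum)
  num <- tapply(cohort$weight * cohort$diabetic_at_baseline, f, sum)
  prev <- as.numeric(num) / as.numeric(den)
  rate_table(grid, prevalence = prev, source = "cohort-estimated")
}

#' Estimate age-specific diabetes incidence
#'
#' Occurrence/exposure estimation of the annual diagnosis rate among the
#' diabetes-free, equivalent to a saturated age-group piecewise-exponential
#' model fitted by maximum likelihood.
#'
#' Two exposure windows are supported. `"retrospective"` (the default)
#' reconstructs history from the reported age at diagnosis, assuming no
#' survival selection: every subject contributes diabetes-free person-years
#' from age 30 to the earlier of diagnosis and baseline age, and prevalent
#' diagnoses are the events. `"followup"` uses the prospective window:
#' diabetes-free subjects at baseline contribute person-years until incident
#' diagnosis, death or end of follow-up, and incident diagnoses are the
#' events.
#'
#' @param cohort a `synthetic_cohort`.
#' @param grid an [age_grid()].
#' @param window `"retrospective"` or `"followup"`.
#' @param weighted use sampling weights (default) or unit weights.
#' @return A partial [rate_table()] with `incidence` filled; person-years
#'   and event tallies are kept in the `"person_years"` attribute.
#' @export
estimate_incidence <- function(cohort, grid,
                               window = c("retrospective", "followup"),
                               weighted = TRUE) {
  stopifnot_grid(grid)
  window <- match.arg(window)
  if (any(cohort$age_at_diagnosis < 30, na.rm = TRUE))
    stop("diagnosis before age 30 violates the type-2 filter")
  w <- if (weighted) cohort$weight else rep(1, nrow(cohort))
  if (window == "retrospective") {
    prevalent <- cohort$diabetic_at_baseline
    exit <- ifelse(prevalent, cohort$age_at_diagnosis,
                   cohort$age_at_baseline)
    event <- ifelse(prevalent, cohort$age_at_diagnosis, NA_real_)
    py <- person_years(rep(30, nrow(cohort)), exit, event, w, grid)
  } else {
    free <- !cohort$diabetic_at_baseline
    fu <- attr(cohort, "spec")$followup_years %||% Inf
    end <- cohort$age_at_baseline + fu
    exit <- pmin(cohort$incident_diagnosis_age,
                 cohort$age_at_death, end, na.rm = TRUE)
    event <- cohort$incident_diagnosis_age
    py <- person_years(cohort$age_at_baseline[free], exit[free],
                       event[free], w[free], grid)
  }
  if (any(py$exposure < 0)) stop("negative person-years")
  rate <- ifelse(py$exposure > 0, py$events / py$exposure, NA_real_)
  rt <- rate_table(grid, incidence = rate, source = "cohort-estimated")
  attr(rt, "person_years") <- py
  rt
}

# Diabetic follow-up window per subject: entry at baseline (prevalent) or
# incident diagnosis, exit at death or end of follow-up. NA when never
# diabetic during follow-up.
diabetic_window <- function(cohort) {
  fu <- attr(cohort, "spec")$followup_years %||% Inf
  end <- cohort$age_at_baseline + fu
  entry <- ifelse(cohort$diabetic_at_baseline, cohort$age_at_baseline,
                  cohort$incident_diagnosis_age)
  exit <- pmin(cohort$age_at_death, end, na.rm = TRUE)
  death_age <- ifelse(!is.na(entry) & cohort$died &
                        cohort$age_at_death <= end + 1e-9,
                      cohort$age_at_death, NA_real_)
  list(entry = entry, exit = exit, death_age = death_age)
}

#' Estimate all-cause mortality of the diabetic population
#'
#' Weighted occurrence/exposure death rates among subjects while diabetic
#' during follow-up: events are deaths of diabetic subjects, exposure the
#' diabetic person-years, split by age group.
#'
#' @inheritParams estimate_incidence
#' @return A partial [rate_table()] with `m_diabetic` filled (and
#'   `q_diabetic` derived with default separation factors).
#' @export
estimate_diabetic_mortality <- function(cohort, grid, weighted = TRUE) {
  stopifnot_grid(grid)
  if (any(cohort$died & cohort$age_at_death < cohort$age_at_baseline,
          na.rm = TRUE))
    stop("death before baseline age")
  w <- if (weighted) cohort$weight else rep(1, nrow(cohort))
  dw <- diabetic_window(cohort)
  py <- person_years(dw$entry, dw$exit, dw$death_age, w, grid)
  rate <- ifelse(py$exposure > 0, py$events / py$exposure, NA_real_)
  rt <- rate_table(grid, m_diabetic = rate,
                   q_diabetic = mx_to_qx(rate, grid$age_width),
                   source = "cohort-estimated")
  attr(rt, "person_years") <- py
  rt
}

#' Cause-specific mortality hazards under competing risks
#'
#' Splits the cohort's all-cause occurrence/exposure death rate into the
#' diabetes-caused and other-caused hazards. Both causes share the same
#' person-years denominator (all follow-up exposure), so the two
#' cause-specific rates sum exactly to the all-cause rate in every group.
#'
#' @inheritParams estimate_incidence
#' @return A data frame with columns `age_start`, `age_width`,
#'   `hazard_diabetes`, `hazard_other`, `hazard_all`, `exposure`,
#'   `events_diabetes`, `events_other`.
#' @export
cause_specific_hazards <- function(cohort, grid, weighted = TRUE) {
  stopifnot_grid(grid)
  if (any(cohort$died & is.na(cohort$cause_of_death)))
    stop("death without a cause-of-death flag")
  w <- if (weighted) cohort$weight else rep(1, nrow(cohort))
  fu <- attr(cohort, "spec")$followup_years %||% Inf
  end <- cohort$age_at_baseline + fu
  exit <- pmin(cohort$age_at_death, end, na.rm = TRUE)
  death_age <- ifelse(cohort$died & cohort$age_at_death <= end + 1e-9,
                      cohort$age_at_death, NA_real_)
  dm <- ifelse(!is.na(death_age) & cohort$cause_of_death == "diabetes",
               death_age, NA_real_)
  ot <- ifelse(!is.na(death_age) & cohort$cause_of_death == "other",
               death_age, NA_real_)
  py_dm <- person_years(cohort$age_at_baseline, exit, dm, w, grid)
  py_ot <- person_years(cohort$age_at_baseline, exit, ot, w, grid)
  expo <- py_dm$exposure
  rate <- function(ev) ifelse(expo > 0, ev / expo, NA_real_)
  data.frame(
    age_start = grid$age_start, age_width = grid$age_width,
    hazard_diabetes = rate(py_dm$events),
    hazard_other = rate(py_ot$events),
    hazard_all = rate(py_dm$events + py_ot$events),
    exposure = expo,
    events_diabetes = py_dm$events, events_other = py_ot$events
  )
}

#' Fill missing rate-table entries from an external source
#'
#' Groups whose cohort-based estimate is missing (empty denominator) must be
#' completed from a national or assumed schedule before projection; missing
#' entries are never silently zero-filled.
#'
#' @param rt a [rate_table()].
#' @param fill a [rate_table()] on the same grid supplying the fallback
#'   values, typically tagged `"national"`.
#' @return The completed rate table; filled rows carry the fill table's
#'   source tag.
#' @export
fill_rate_table <- function(rt, fill) {
  if (!identical(rt$age_start, fill$age_start))
    stop("rate tables are on different grids")
  out <- rt
  cols <- c("prevalence", "incidence", "m_diabetic", "q_diabetic")
  bare <- rowSums(!is.na(rt[cols])) == 0   # rows with no estimate at all
  for (col in cols) {
    miss <- is.na(out[[col]]) & !is.na(fill[[col]])
    out[[col]][miss] <- fill[[col]][miss]
  }
  out$source[bare] <- fill$source[bare]
  out
}

#' @rdname rate_table
#' @param rt a rate table to write.
#' @param path CSV path.
#' @export
write_rate_table_csv <- function(rt, path) {
  utils::write.csv(as.data.frame(rt), path, row.names = FALSE)
  invisible(path)
}

#' @rdname rate_table
#' @export
read_rate_table_csv <- function(path) {
  rt <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_rate_table(rt)
  class(rt) <- c("rate_table", "data.frame")
  rt
}
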
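#' Two-part model of annual healthcare utilization
#'
#' Fits the health-economics two-part model to annual episode counts: part
#' one is a logistic regression for any use over a calendar year, part two a
#' model for the number of episodes among users. Covariates are diabetes
#' status and elderly age band (60-69 / 70-79 / 80+). The expected annual
#' episodes per stratum (`strata_means`) are computed as
#' `P(any use) * E(episodes | use)` with both parts saturated by stratum, so
#' they equal the stratum empirical means exactly; the regression
#' coefficients summarize the same data parsimoniously and are what
#' parameter-recovery checks target.
#'
#' @param cohort a `synthetic_cohort` with the utilization column for the
#'   service (see [generate_utilization()]).
#' @param service `"hospitalization"` or `"outpatient"`.
#' @param intensity `"saturated"` (default; stratum means of the positive
#'   part) or `"loglinear"` (Poisson log-link regression of `count - 1` on
#'   the covariates among users, mirroring the generating model).
#' @param weighted use sampling weights (default).
#' @return An object of class `two_part` with components `service`,
#'   `participation` (fitted logistic `glm`), `intensity_fit` (the Poisson
#'   `glm`, when requested), `strata_means` (data frame `diabetic`,
#'   `age_band`, `p_use`, `mean_pos`, `mean_count`), and `separation`
#'   (strata with all-zero or all-positive use, for which the empirical
#'   fallback is used).
#' @seealso [expected_cost_per_capita()], [project_costs()]
#' @export
two_part <- function(cohort, service = c("hospitalization", "outpatient"),
                     intensity = c("saturated", "loglinear"),
                     weighted = TRUE) {
  service <- match.arg(service)
  intensity <- match.arg(intensity)
  col <- if (service == "hospitalization") "hospitalizations"
         else "outpatient_visits"
  if (is.null(cohort[[col]]))
    stop("cohort lacks the '", col, "' utilization column")
  y <- cohort[[col]]
  if (any(is.na(y))) stop("utilization counts contain NA")
  w <- if (weighted) cohort$weight else rep(1, nrow(cohort))
  diabetic <- as.logical(cohort$diabetic_at_baseline)
  band <- cost_age_band(cohort$age_at_baseline)
  if (!any(diabetic) || all(diabetic))
    stop("both diabetic and non-diabetic strata must be populated")
  use <- as.numeric(y > 0)
  dat <- data.frame(use = use, y = y, diabetic = diabetic, band = band,
                    w = w)

  # per-stratum empirical decomposition (saturated both parts)
  key <- interaction(diabetic, band, drop = FALSE)
  agg <- function(v, wt) {
    num <- tapply(v * wt, key, sum); den <- tapply(wt, key, sum)
    as.numeric(num) / as.numeric(den)
  }
  p_use <- agg(use, w)
  mean_pos <- vapply(levels(key), function(l) {
    sel <- key == l & use == 1
    if (!any(sel)) return(0)
    sum(y[sel] * w[sel]) / sum(w[sel])
  }, numeric(1))
  parts <- do.call(rbind, strsplit(levels(key), ".", fixed = TRUE))
  strata_means <- data.frame(
    diabetic = as.logical(parts[, 1]), age_band = parts[, 2],
    p_use = p_use, mean_pos = mean_pos,
    mean_count = p_use * mean_pos, stringsAsFactors = FALSE
  )

  sep <- levels(key)[p_use %in% c(0, 1) | is.na(p_use)]
  if (length(sep))
    warning("separation in strata ", paste(sep, collapse = ", "),
            "; stratum empirical means are used for these cells")

  # sampling weights are generally non-integer; the warnings glm emits about
  # non-integer successes are expected and harmless for point estimation
  part1 <- suppressWarnings(
    stats::glm(use ~ diabetic + band, family = stats::binomial(),
               data = dat, weights = w))
  part2 <- NULL
  if (intensity == "loglinear") {
    users <- dat[dat$use == 1, ]
    part2 <- suppressWarnings(
      stats::glm(I(y - 1) ~ diabetic + band,
                 family = stats::poisson(), data = users,
                 weights = users$w))
  }
  structure(list(service = service, participation = part1,
                 intensity_fit = part2, intensity = intensity,
                 strata_means = strata_means, separation = sep,
                 n = nrow(cohort)),
            class = "two_part")
}

cost_age_band <- function(age) {
  factor(ifelse(age < 70, "60-69", ifelse(age < 80, "70-79", "80+")),
         levels = c("60-69", "70-79", "80+"))
}

#' @export
print.two_part <- function(x, ...) {
  cat("Two-part utilization model -", x$service,
      sprintf("(n = %d)\n", x$n))
  cat("Participation (logit):\n")
  print(round(stats::coef(x$participation), 3))
  if (!is.null(x$intensity_fit)) {
    cat("Intensity (log-linear, episodes - 1 among users):\n")
    print(round(stats::coef(x$intensity_fit), 3))
  }
  cat("Expected annual episodes by stratum:\n")
  print(x$strata_means, row.names = FALSE)
  invisible(x)
}

#' @export
coef.two_part <- function(object, ...) {
  list(participation = stats::coef(object$participation),
       intensity = if (!is.null(object$intensity_fit))
         stats::coef(object$intensity_fit))
}

#' Expected annual episodes for given strata
#'
#' @param object a [two_part()] fit.
#' @param newdata data frame with columns `diabetic` and `age_band`
#'   (defaults to all strata).
#' @param ... unused.
#' @return Numeric vector of expected annual episode counts.
#' @export
predict.two_part <- function(object, newdata = NULL, ...) {
  sm <- object$strata_means
  if (is.null(newdata)) return(stats::setNames(
    sm$mean_count, paste(ifelse(sm$diabetic, "diabetic", "nondiabetic"),
                         sm$age_band)))
  m <- match(paste(newdata$diabetic, newdata$age_band),
             paste(sm$diabetic, sm$age_band))
  if (any(is.na(m))) stop("unknown stratum requested")
  sm$mean_count[m]
}

#' Unit cost table
#'
#' Provider-perspective cost per episode, in 2011 USD, for each service.
#' The defaults are synthetic stand-ins of the order of magnitude of social-
#' security unit costs (total service expenses divided by total production).
#'
#' @param hospitalization cost per hospitalization episode (> 0).
#' @param outpatient cost per outpatient consultation (> 0).
#' @return Named numeric vector of class `unit_cost_table`.
#' @export
unit_cost_table <- function(hospitalization = 2500, outpatient = 60) {
  if (hospitalization <= 0 || outpatient <= 0)
    stop("unit costs must be positive")
  structure(c(hospitalization = hospitalization, outpatient = outpatient),
            class = "unit_cost_table")
}

#' Expected per-capita annual cost by stratum
#'
#' Multiplies the two-part expected annual episodes by the service unit
#' cost.
#'
#' @param fit a [two_part()] fit.
#' @param unit a [unit_cost_table()] (or a single positive number taken as
#'   the cost per episode of the fit's service).
#' @return Data frame `diabetic`, `age_band`, `episodes`, `cost`
#'   (2011 USD / person / year).
#' @export
expected_cost_per_capita <- function(fit, unit) {
  uc <- if (inherits(unit, "unit_cost_table")) {
    key <- if (fit$service == "hospitalization") "hospitalization"
           else "outpatient"
    unname(unit[key])
  } else as.numeric(unit)
  if (length(uc) != 1L || is.na(uc) || uc < 0)
    stop("unit cost must be a single non-negative number")
  sm <- fit$strata_means
  data.frame(diabetic = sm$diabetic, age_band = sm$age_band,
             episodes = sm$mean_count, cost = sm$mean_count * uc,
             stringsAsFactors = FALSE)
}

#' Project total healthcare costs along a population projection
#'
#' Applies constant per-capita utilization and cost patterns to projected
#' diabetic / non-diabetic counts: the annual total cost per year is the sum
#' over elderly age groups of counts times the stratum per-capita cost, kept
#' separately for the diabetic and non-diabetic populations, together with
#' the diabetic share of the total.
#'
#' @param states list of [population_state()]s.
#' @param per_capita result of [expected_cost_per_capita()].
#' @param service label carried into the output.
#' @param min_age groups below this age are excluded (default 60; the cost
#'   model describes elderly utilization only).
#' @return Data frame of class `cost_projection`: `year`, `service`,
#'   `cost_diabetic`, `cost_nondiabetic`, `diabetic_share`.
#' @export
project_costs <- function(states, per_capita, service, min_age = 60) {
  rows <- lapply(states, function(st) {
    sel <- which(st$age_start >= min_age)
    band <- cost_age_band(st$age_start[sel])
    cost_for <- function(diab, counts) {
      m <- match(paste(diab, band), paste(per_capita$diabetic,
                                          per_capita$age_band))
      if (any(is.na(m)))
        stop("per-capita costs missing stratum ",
             paste(band[is.na(m)], collapse = ", "))
      sum(counts * per_capita$cost[m])
    }
    cd <- cost_for(TRUE, st$n_diabetic[sel])
    cn <- cost_for(FALSE, st$n_nondiabetic[sel])
    data.frame(year = state_year(st), service = service,
               cost_diabetic = cd, cost_nondiabetic = cn,
               diabetic_share = if (cd + cn > 0) cd / (cd + cn) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("cost_projection", "data.frame")
  out
}
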
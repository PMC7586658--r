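#' Abridged period life table
#'
#' Standard abridged construction from a schedule of central death rates:
#' interval death probabilities via [mx_to_qx()], survivors from a radix of
#' 100,000, person-years `nLx = n * l(x+n) + nax * ndx` for closed groups
#' and `lx / mx` for the open group, and remaining life expectancy
#' `ex = Tx / lx`.
#'
#' @param mx central death rates per age group (open group must be > 0).
#' @param grid an [age_grid()].
#' @param nax separation factors for the closed groups (default `n/2`;
#'   supply Coale-Demeny-style values for infant/child groups when building
#'   tables from birth). The open group's entry is ignored.
#' @param radix starting cohort size (default 100,000).
#' @return A data frame of class `life_table` with columns `x`, `n`, `mx`,
#'   `nax`, `qx`, `lx`, `ndx`, `nLx`, `Tx`, `ex`.
#' @examples
#' g <- age_grid(60, 95)
#' lt <- life_table(c(0.01, 0.016, 0.025, 0.04, 0.065, 0.105, 0.17, 0.28), g)
#' life_expectancy(lt, 60)
#' @export
life_table <- function(mx, grid, nax = NULL, radix = 1e5) {
  stopifnot_grid(grid)
  k <- nrow(grid)
  if (length(mx) != k) stop("mx must have one value per age group")
  if (any(is.na(mx)) || any(mx < 0)) stop("mx must be non-negative")
  if (mx[k] <= 0) stop("open-group rate must be positive to close the table")
  n <- grid$age_width
  if (is.null(nax)) nax <- ifelse(is.finite(n), n / 2, NA_real_)
  if (length(nax) != k) stop("nax must have one value per age group")
  qx <- mx_to_qx(mx, n, ifelse(is.finite(n), nax, 1))
  lx <- radix * cumprod(c(1, 1 - qx[-k]))
  ndx <- lx * qx
  lnext <- c(lx[-1], 0)
  nLx <- ifelse(is.finite(n), n * lnext + nax * ndx, lx[k] / mx[k])
  nLx[k] <- lx[k] / mx[k]
  Tx <- rev(cumsum(rev(nLx)))
  ex <- ifelse(lx > 0, Tx / lx, NA_real_)
  lt <- data.frame(x = grid$age_start, n = n, mx = mx, nax = nax, qx = qx,
                   lx = lx, ndx = ndx, nLx = nLx, Tx = Tx, ex = ex)
  rownames(lt) <- age_group_labels(grid)
  class(lt) <- c("life_table", "data.frame")
  lt
}

#' @export
print.life_table <- function(x, digits = 4, ...) {
  cat("Abridged life table (", nrow(x), " groups, e",
      x$x[1], " = ", round(x$ex[1], 2), " years)\n", sep = "")
  print.data.frame(format(x, digits = digits), ...)
  invisible(x)
}

#' Remaining life expectancy at an exact age
#'
#' @param table a [life_table()].
#' @param age an age present in the table's grid (e.g. 0 or 60).
#' @return `ex` at that age, in years.
#' @export
life_expectancy <- function(table, age) {
  i <- match(age, table$x)
  if (is.na(i)) stop("age ", age, " is not a group boundary of this table")
  table$ex[i]
}

#' Counterfactual mortality schedules for the diabetes scenarios
#'
#' Builds the per-age central-rate schedule of each life-table scenario:
#' \describe{
#'   \item{`all_cause`}{the schedule unchanged;}
#'   \item{`delete_dm2`}{proportional cause deletion,
#'     `mx * (1 - f)`, with `f` the registry fraction of deaths attributed
#'     to diabetes;}
#'   \item{`delete_dm2_add_model`}{cause deletion plus re-insertion of the
#'     diabetes-caused hazard estimated from a competing-risks model,
#'     `mx * (1 - f) + h`.}
#' }
#' With an age-constant observed pattern both `f` and `h` are held constant
#' over forecast time.
#'
#' @param all_cause_mx all-cause central rates per age group.
#' @param dm2_registry_fraction fractions in `[0, 1)`, zero below age 30.
#' @param dm2_model_hazard diabetes-caused hazard (>= 0) from the
#'   competing-risks estimate, zero below age 30; required for the
#'   re-insertion scenario.
#' @param label one of `"all_cause"`, `"delete_dm2"`,
#'   `"delete_dm2_add_model"`.
#' @return List of class `scenario_schedule` with elements `label` and `mx`.
#' @export
scenario_schedule <- function(all_cause_mx,
                              dm2_registry_fraction = 0,
                              dm2_model_hazard = 0,
                              label = c("all_cause", "delete_dm2",
                                        "delete_dm2_add_model")) {
  label <- match.arg(label)
  k <- length(all_cause_mx)
  f <- rep_len(dm2_registry_fraction, k)
  h <- rep_len(dm2_model_hazard, k)
  if (any(f < 0) || any(f >= 1)) stop("fractions must lie in [0, 1)")
  if (any(h < 0)) stop("model hazard must be >= 0")
  mx <- switch(label,
               all_cause = all_cause_mx,
               delete_dm2 = all_cause_mx * (1 - f),
               delete_dm2_add_model = all_cause_mx * (1 - f) + h)
  if (mx[k] <= 0)
    stop("scenario schedule is non-positive in the open group")
  structure(list(label = label, mx = mx), class = "scenario_schedule")
}

#' Years of life lost to diabetes at age 60
#'
#' Difference between the all-cause life expectancy at 60 and the life
#' expectancy at 60 under the delete-and-reinsert counterfactual (diabetes
#' removed as a registry cause, model-based diabetes-caused mortality added
#' back). A negative value (possible when the re-inserted hazard is smaller
#' than the deleted mortality) is returned as is, with a message.
#'
#' @param table_all all-cause [life_table()].
#' @param table_scenario [life_table()] of the counterfactual scenario.
#' @param age evaluation age (default 60).
#' @return Years of life lost (years).
#' @export
yll_at_60 <- function(table_all, table_scenario, age = 60) {
  if (!identical(table_all$x, table_scenario$x))
    stop("life tables are on different grids")
  yll <- life_expectancy(table_all, age) -
    life_expectancy(table_scenario, age)
  if (is.finite(yll) && yll < 0)
    message("negative years of life lost: the counterfactual schedule has ",
            "lower mortality than the all-cause schedule")
  yll
}

# Vectorized life expectancy at `age` for a matrix of schedules
# (ages x trajectories). Same arithmetic as life_table(), columnwise.
e_at_matrix <- function(mx_mat, grid, age, nax = NULL) {
  k <- nrow(grid)
  n <- grid$age_width
  if (is.null(nax)) nax <- ifelse(is.finite(n), n / 2, 1)
  qx <- n * mx_mat / (1 + (n - nax) * mx_mat)
  qx[!is.finite(n), ] <- 1
  qx <- pmin(qx, 1)
  lx <- apply(rbind(1, 1 - qx[-k, , drop = FALSE]), 2, cumprod)
  if (k == 1L) lx <- matrix(1, 1, ncol(mx_mat))
  ndx <- lx * qx
  lnext <- rbind(lx[-1, , drop = FALSE], 0)
  nLx <- n * lnext + nax * ndx
  nLx[k, ] <- lx[k, ] / mx_mat[k, ]
  i <- match(age, grid$age_start)
  if (is.na(i)) stop("age not on grid")
  Tx <- apply(nLx[i:k, , drop = FALSE], 2, sum)
  Tx / lx[i, ]
}

#' Forecast-based confidence interval for years of life lost
#'
#' Propagates Lee-Carter forecast uncertainty into the years-of-life-lost
#' estimate: for each simulated mortality trajectory at the target year, the
#' all-cause and delete-and-reinsert schedules are built, both life tables
#' computed, and their `e60` difference taken; the point estimate and
#' interval are percentiles across trajectories.
#'
#' @param forecast an [lc_forecast()] (at least 100 trajectories).
#' @param dm2_registry_fraction,dm2_model_hazard as in
#'   [scenario_schedule()], per age group of the forecast grid.
#' @param year target forecast year.
#' @param age evaluation age (default 60).
#' @param level interval coverage (default 0.95).
#' @param nax optional separation factors.
#' @return List with `median`, `lower`, `upper` (years of life lost), and
#'   `samples` (per-trajectory values).
#' @export
yll_confidence_interval <- function(forecast, dm2_registry_fraction,
                                    dm2_model_hazard, year, age = 60,
                                    level = 0.95, nax = NULL) {
  if (!inherits(forecast, "lc_forecast"))
    stop("`forecast` must be an lc_forecast")
  if (forecast$n_sims < 100)
    stop("at least 100 trajectories are required for interval reporting")
  h <- match(year, forecast$years)
  if (is.na(h)) stop("year ", year, " is not in the forecast horizon")
  fit <- forecast$fit
  kt <- forecast$kt_paths[, h]
  mx_all <- exp(outer(fit$bx, kt) + fit$ax)   # ages x trajectories
  k <- length(fit$ax)
  f <- rep_len(dm2_registry_fraction, k)
  hz <- rep_len(dm2_model_hazard, k)
  if (any(f < 0) || any(f >= 1)) stop("fractions must lie in [0, 1)")
  mx_cf <- mx_all * (1 - f) + hz
  e_all <- e_at_matrix(mx_all, fit$grid, age, nax)
  e_cf <- e_at_matrix(mx_cf, fit$grid, age, nax)
  samples <- e_all - e_cf
  alpha <- (1 - level) / 2
  qs <- stats::quantile(samples, probs = c(alpha, 0.5, 1 - alpha),
                        names = FALSE)
  list(median = qs[2], lower = qs[1], upper = qs[3], samples = samples)
}

#' Table of forecast life expectancy at 60 under the diabetes scenarios
#'
#' For each target year, computes the median and percentile interval of
#' `e60` under the all-cause schedule, the diabetes-deleted schedule, and
#' the delete-and-reinsert schedule, plus the years of life lost (all-cause
#' minus delete-and-reinsert), all across the forecast trajectories.
#'
#' @inheritParams yll_confidence_interval
#' @param years target forecast years.
#' @return Data frame with columns `year`, `quantity` (one of
#'   `e60_all_cause`, `e60_delete_dm2`, `e60_delete_add_model`, `yll`),
#'   `estimate`, `lower`, `upper` and a formatted `cell`
#'   `"estimate (lower-upper)"`.
#' @export
e60_scenario_table <- function(forecast, dm2_registry_fraction,
                               dm2_model_hazard, years, age = 60,
                               level = 0.95, nax = NULL) {
  fit <- forecast$fit
  k <- length(fit$ax)
  f <- rep_len(dm2_registry_fraction, k)
  hz <- rep_len(dm2_model_hazard, k)
  alpha <- (1 - level) / 2
  rows <- list()
  for (yr in years) {
    h <- match(yr, forecast$years)
    if (is.na(h)) stop("year ", yr, " is not in the forecast horizon")
    kt <- forecast$kt_paths[, h]
    mx_all <- exp(outer(fit$bx, kt) + fit$ax)
    sets <- list(
      e60_all_cause = mx_all,
      e60_delete_dm2 = mx_all * (1 - f),
      e60_delete_add_model = mx_all * (1 - f) + hz
    )
    es <- lapply(sets, e_at_matrix, grid = fit$grid, age = age, nax = nax)
    es$yll <- es$e60_all_cause - es$e60_delete_add_model
    for (nm in names(es)) {
      qs <- stats::quantile(es[[nm]], probs = c(alpha, 0.5, 1 - alpha),
                            names = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        year = yr, quantity = nm, estimate = qs[2], lower = qs[1],
        upper = qs[3],
        cell = sprintf("%.2f (%.2f-%.2f)", qs[2], qs[1], qs[3]),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
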
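#' Age-by-year mortality surface
#'
#' Matrix of central death rates with rows indexed by an [age_grid()] and
#' columns by calendar years; the input to Lee-Carter estimation. Rates must
#' be strictly positive (zeros must be imputed upstream).
#'
#' @param m matrix of central death rates (> 0), ages by years.
#' @param grid an [age_grid()] with one row per matrix row.
#' @param years calendar years, one per matrix column.
#' @param deaths,exposures optional matching matrices (>= 0), enabling the
#'   second-stage death-matching adjustment in [lc()].
#' @return An object of class `mortality_surface`.
#' @export
mortality_surface <- function(m, grid, years, deaths = NULL,
                              exposures = NULL) {
  stopifnot_grid(grid)
  m <- as.matrix(m)
  if (nrow(m) != nrow(grid) || ncol(m) != length(years))
    stop("rate matrix dimensions do not match grid/years")
  if (any(!is.finite(m)) || any(m <= 0))
    stop("central death rates must be finite and strictly positive")
  for (x in list(deaths, exposures))
    if (!is.null(x) && !identical(dim(as.matrix(x)), dim(m)))
      stop("deaths/exposures must match the rate matrix dimensions")
  dimnames(m) <- list(age_group_labels(grid), years)
  structure(list(m = m, grid = grid, years = as.integer(years),
                 deaths = deaths, exposures = exposures),
            class = "mortality_surface")
}

#' @export
print.mortality_surface <- function(x, ...) {
  cat("Mortality surface:", nrow(x$m), "age groups x", ncol(x$m),
      "years (", min(x$years), "-", max(x$years), ")\n")
  invisible(x)
}

#' Restrict a mortality surface to a year window
#'
#' Early decades with atypically steep declines (e.g. the tail of an infant-
#' mortality transition) are routinely excluded before fitting, so the
#' random-walk drift reflects only the recent regime.
#'
#' @param surface a [mortality_surface()].
#' @param from,to first and last calendar year to keep.
#' @return The restricted surface.
#' @export
window_surface <- function(surface, from = min(surface$years),
                           to = max(surface$years)) {
  keep <- surface$years >= from & surface$years <= to
  if (!any(keep)) stop("empty year window")
  mortality_surface(surface$m[, keep, drop = FALSE], surface$grid,
                    surface$years[keep],
                    if (!is.null(surface$deaths))
                      surface$deaths[, keep, drop = FALSE],
                    if (!is.null(surface$exposures))
                      surface$exposures[, keep, drop = FALSE])
}

#' Fit the Lee-Carter mortality model
#'
#' Estimates the log-bilinear decomposition
#' \deqn{\log m(x,t) = a_x + b_x k_t + \epsilon_{x,t}}
#' with \eqn{a_x} the row means of the log rates and \eqn{(b_x, k_t)} the
#' first singular component of the centred log-rate matrix, under the usual
#' identifiability constraints \eqn{\sum_x b_x = 1}, \eqn{\sum_t k_t = 0}.
#' The sign is fixed so that \eqn{\sum_x b_x > 0}. The period index is then
#' summarized by a random walk with drift: the drift is
#' \eqn{(k_T - k_1)/(T-1)}, its innovation standard deviation the ML
#' estimate from the first differences.
#'
#' When the surface carries deaths and exposures (and
#' `adjust_kt = TRUE`), a second-stage adjustment re-solves each \eqn{k_t}
#' so that predicted total deaths match observed deaths in every year, as in
#' the classical two-stage procedure.
#'
#' @param surface a [mortality_surface()] (at least 3 years, 2 age groups).
#' @param years optional year window `c(from, to)` applied before fitting.
#' @param adjust_kt apply the death-matching second stage (default: only
#'   when deaths and exposures are available).
#' @return An object of class `lc`: list with `ax`, `bx`, `kt`, `drift`,
#'   `sigma` (innovation SD), `se_drift`, `explained` (share of variance of
#'   the centred matrix captured by the first singular component), `grid`,
#'   `years`, `degenerate` flag.
#' @examples
#' surf <- generate_mortality_surface(surface_spec(seed = 3))
#' fit <- lc(surf, years = c(1980, 2010))
#' fit
#' @export
lc <- function(surface, years = NULL, adjust_kt = NULL) {
  if (!inherits(surface, "mortality_surface"))
    stop("`surface` must be a mortality_surface")
  if (!is.null(years))
    surface <- window_surface(surface, years[1], years[2])
  logm <- log(surface$m)
  nt <- ncol(logm); nx <- nrow(logm)
  if (nt < 3L) stop("need at least 3 years")
  if (nx < 2L) stop("need at least 2 age groups")
  ax <- rowMeans(logm)
  cen <- logm - ax
  degenerate <- sum(cen^2) < 1e-24
  if (degenerate) {
    warning("surface is constant over time; returning a flat fit")
    bx <- rep(1 / nx, nx)
    kt <- rep(0, nt)
    explained <- 1
  } else {
    sv <- svd(cen)
    u1 <- sv$u[, 1]; v1 <- sv$v[, 1]; d1 <- sv$d[1]
    s <- sum(u1)
    if (abs(s) < 1e-12) s <- if (mean(u1) >= 0) 1e-12 else -1e-12
    bx <- u1 / s
    kt <- d1 * v1 * s
    explained <- d1^2 / sum(sv$d^2)
    # absorb the kt mean into the level so the constraints hold exactly
    ax <- ax + bx * mean(kt)
    kt <- kt - mean(kt)
  }
  if (is.null(adjust_kt))
    adjust_kt <- !is.null(surface$deaths) && !is.null(surface$exposures)
  if (adjust_kt && !degenerate) {
    if (is.null(surface$deaths) || is.null(surface$exposures))
      stop("death-matching adjustment needs deaths and exposures")
    for (t in seq_len(nt)) {
      Dt <- sum(surface$deaths[, t])
      Et <- surface$exposures[, t]
      f <- function(k) sum(Et * exp(ax + bx * k)) - Dt
      kt[t] <- stats::uniroot(f, interval = kt[t] + c(-20, 20),
                              extendInt = "yes", tol = 1e-10)$root
    }
    ax <- ax + bx * mean(kt)
    kt <- kt - mean(kt)
  }
  dk <- diff(kt)
  drift <- if (nt > 1) (kt[nt] - kt[1]) / (nt - 1) else 0
  sigma <- if (nt > 2) sqrt(mean((dk - drift)^2)) else 0
  structure(list(ax = ax, bx = bx, kt = kt, drift = drift, sigma = sigma,
                 se_drift = if (nt > 1) sigma / sqrt(nt - 1) else NA_real_,
                 explained = explained, grid = surface$grid,
                 years = surface$years, degenerate = degenerate),
            class = "lc")
}

#' @export
print.lc <- function(x, ...) {
  cat("Lee-Carter fit:", length(x$ax), "age groups,",
      length(x$years), "years (", min(x$years), "-", max(x$years), ")\n")
  cat(sprintf("  drift %.4f (se %.4f), innovation sd %.4f\n",
              x$drift, x$se_drift, x$sigma))
  cat(sprintf("  first singular component explains %.1f%% of variance\n",
              100 * x$explained))
  invisible(x)
}

#' @export
summary.lc <- function(object, ...) {
  structure(list(fit = object), class = "summary.lc")
}

#' @export
print.summary.lc <- function(x, ...) {
  print(x$fit)
  cat("\nax (log level):\n"); print(round(x$fit$ax, 3))
  cat("bx (sensitivity, sum = 1):\n"); print(round(x$fit$bx, 4))
  cat("kt (period index, sum = 0):\n"); print(round(x$fit$kt, 3))
  invisible(x)
}

#' @export
coef.lc <- function(object, ...) {
  list(ax = object$ax, bx = object$bx, kt = object$kt,
       drift = object$drift, sigma = object$sigma)
}

#' Fitted central death rates of a Lee-Carter model
#' @param object an [lc()] fit.
#' @param ... unused.
#' @return Matrix of fitted rates, ages by years.
#' @export
fitted.lc <- function(object, ...) {
  exp(outer(object$bx, object$kt) + object$ax)
}

#' Stochastic Lee-Carter mortality forecast
#'
#' Simulates the period index forward as a random walk with drift
#' (optionally resampling the drift from its estimation distribution, which
#' propagates drift uncertainty into the intervals) and maps each trajectory
#' to rates through the fitted \eqn{\exp(a_x + b_x k_t)}. Median and
#' percentile surfaces are computed elementwise across simulations.
#'
#' @param fit an [lc()] fit.
#' @param horizon number of years ahead (default 25).
#' @param n_sims number of trajectories (>= 2 for intervals).
#' @param level central interval coverage (default 0.95).
#' @param drift_uncertainty include drift estimation error (default TRUE).
#' @param seed integer seed.
#' @return An object of class `lc_forecast`: `years` (forecast years),
#'   `kt_paths` (`n_sims` x `horizon`), `median`, `lower`, `upper` rate
#'   surfaces (ages x years), the `fit`, `level` and `seed`.
#' @export
lc_forecast <- function(fit, horizon = 25, n_sims = 1000, level = 0.95,
                        drift_uncertainty = TRUE, seed = 1L) {
  if (!inherits(fit, "lc")) stop("`fit` must be an lc object")
  if (horizon < 1) stop("horizon must be >= 1")
  if (n_sims < 2) stop("n_sims must be >= 2 to form intervals")
  with_seed(seed, {
    k_last <- fit$kt[length(fit$kt)]
    drifts <- if (drift_uncertainty && is.finite(fit$se_drift))
      stats::rnorm(n_sims, fit$drift, fit$se_drift)
    else rep(fit$drift, n_sims)
    innov <- matrix(stats::rnorm(n_sims * horizon, 0, fit$sigma),
                    nrow = n_sims)
    kt_paths <- k_last + t(apply(innov + drifts, 1, cumsum))
    if (horizon == 1L) kt_paths <- matrix(kt_paths, ncol = 1L)
    years <- max(fit$years) + seq_len(horizon)
    alpha <- (1 - level) / 2
    nx <- length(fit$ax)
    rate_q <- function(prob) {
      out <- matrix(NA_real_, nx, horizon)
      for (h in seq_len(horizon)) {
        kq <- stats::quantile(kt_paths[, h], probs = c(prob, 1 - prob),
                              names = FALSE)
        # elementwise: bx may in principle change sign, so take min/max
        lo <- exp(fit$ax + fit$bx * kq[1])
        hi <- exp(fit$ax + fit$bx * kq[2])
        out[, h] <- if (prob <= 0.5) pmin(lo, hi) else pmax(lo, hi)
      }
      out
    }
    med <- exp(outer(fit$bx, apply(kt_paths, 2, stats::median)) + fit$ax)
    lower <- rate_q(alpha)
    upper <- rate_q(1 - alpha)
    dimnames(med) <- dimnames(lower) <- dimnames(upper) <-
      list(age_group_labels(fit$grid), years)
    structure(list(years = years, kt_paths = kt_paths, median = med,
                   lower = lower, upper = upper, fit = fit, level = level,
                   n_sims = n_sims, seed = seed),
              class = "lc_forecast")
  })
}

#' @export
print.lc_forecast <- function(x, ...) {
  cat("Lee-Carter forecast:", x$n_sims, "trajectories,",
      length(x$years), "years (", min(x$years), "-", max(x$years), "),",
      sprintf("%.0f%% intervals\n", 100 * x$level))
  invisible(x)
}

#' Rate schedule of a forecast at one year
#'
#' @param forecast an [lc_forecast()].
#' @param year a forecast year.
#' @param which `"median"`, `"lower"` or `"upper"`.
#' @return Numeric vector of central death rates per age group.
#' @export
forecast_schedule <- function(forecast, year,
                              which = c("median", "lower", "upper")) {
  which <- match.arg(which)
  j <- match(year, forecast$years)
  if (is.na(j)) stop("year ", year, " is not in the forecast horizon")
  forecast[[which]][, j]
}

#' Delete a cause of death from a mortality surface
#'
#' Proportional cause deletion: `m'(x,t) = m(x,t) * (1 - f(x))`, with `f`
#' the age-specific fraction of deaths attributed to the cause. Used to
#' build the non-diabetes mortality stream before fitting and forecasting.
#'
#' @param surface a [mortality_surface()].
#' @param fraction_by_age per-age-group fractions in `[0, 1)`.
#' @return The cause-deleted [mortality_surface()].
#' @export
cause_deleted_surface <- function(surface, fraction_by_age) {
  if (length(fraction_by_age) != nrow(surface$m))
    stop("fraction_by_age must have one value per age group")
  if (any(fraction_by_age < 0) || any(fraction_by_age >= 1))
    stop("fractions must lie in [0, 1)")
  mortality_surface(surface$m * (1 - fraction_by_age), surface$grid,
                    surface$years, surface$deaths, surface$exposures)
}

#' @rdname mortality_surface
#' @param surface surface to write.
#' @param path CSV path (rows age groups, columns years).
#' @export
write_surface_csv <- function(surface, path) {
  df <- data.frame(age_start = surface$grid$age_start,
                   age_width = surface$grid$age_width,
                   surface$m, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname mortality_surface
#' @export
read_surface_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  grid <- df[, c("age_start", "age_width")]
  class(grid) <- c("age_grid", "data.frame")
  years <- as.integer(sub("^X", "", colnames(df)[-(1:2)]))
  mortality_surface(as.matrix(df[, -(1:2)]), grid, years)
}
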
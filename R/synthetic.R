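#' Specification of a synthetic elderly cohort
#'
#' Describes the ground-truth parameters from which [generate_cohort()]
#' simulates a longitudinal survey cohort: a baseline wave of community-
#' dwelling elderly with sampling weights, self-reported diabetes with age
#' at diagnosis, and mortality follow-up with cause-of-death flags. The
#' defaults emulate a nationally representative three-wave study of about
#' 2800 persons aged 60+ interviewed around 2004-2006 with registry
#' follow-up for just over a decade.
#'
#' Schedules (`prevalence_by_age`, `incidence_by_age`,
#' `baseline_mortality_by_age`) are numeric vectors aligned to `grid`.
#'
#' @param n_subjects number of subjects (default 2827).
#' @param baseline_year calendar year of the baseline wave.
#' @param age_range closed range of baseline ages in years.
#' @param sex_ratio fraction female in (0, 1).
#' @param grid [age_grid()] indexing the rate schedules.
#' @param prevalence_by_age baseline diabetes prevalence per age group.
#' @param incidence_by_age annual diagnosis rate per age group (diabetes-free
#'   person-years at risk).
#' @param baseline_mortality_by_age annual all-cause mortality hazard for the
#'   non-diabetic population per age group.
#' @param hr_diabetes_mortality hazard ratio (> 0) multiplying baseline
#'   mortality for diabetic subjects.
#' @param dm2_death_fraction probability that a diabetic subject's death is
#'   certified with diabetes as the underlying cause.
#' @param followup_years length of mortality follow-up.
#' @param weight_dispersion log-scale standard deviation of the lognormal
#'   sampling weights (0 gives unit weights); weights are normalized to
#'   mean 1.
#' @param seed integer seed driving all randomness.
#' @return A validated list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 2827,
                        baseline_year = 2005,
                        age_range = c(60, 104),
                        sex_ratio = 0.525,
                        grid = age_grid(60, 95),
                        prevalence_by_age = c(0.20, 0.22, 0.23, 0.23,
                                              0.20, 0.18, 0.16, 0.15),
                        incidence_by_age = c(0.012, 0.012, 0.010, 0.009,
                                             0.007, 0.005, 0.004, 0.003),
                        baseline_mortality_by_age = c(0.010, 0.016, 0.025,
                                                      0.040, 0.065, 0.105,
                                                      0.170, 0.280),
                        hr_diabetes_mortality = 1.6,
                        dm2_death_fraction = 0.30,
                        followup_years = 12,
                        weight_dispersion = 0.3,
                        seed = 1L) {
  spec <- list(
    n_subjects = n_subjects, baseline_year = baseline_year,
    age_range = age_range, sex_ratio = sex_ratio, grid = grid,
    prevalence_by_age = prevalence_by_age,
    incidence_by_age = incidence_by_age,
    baseline_mortality_by_age = baseline_mortality_by_age,
    hr_diabetes_mortality = hr_diabetes_mortality,
    dm2_death_fraction = dm2_death_fraction,
    followup_years = followup_years,
    weight_dispersion = weight_dispersion, seed = seed
  )
  validate_cohort_spec(spec)
  class(spec) <- "cohort_spec"
  spec
}

validate_cohort_spec <- function(spec) {
  stopifnot_grid(spec$grid)
  k <- nrow(spec$grid)
  if (!is.numeric(spec$n_subjects) || spec$n_subjects <= 0)
    stop("n_subjects must be a positive integer")
  if (k == 0L) stop("empty age grid")
  if (spec$hr_diabetes_mortality <= 0)
    stop("hr_diabetes_mortality must be > 0")
  for (nm in c("prevalence_by_age", "incidence_by_age",
               "baseline_mortality_by_age")) {
    v <- spec[[nm]]
    if (length(v) != k) stop(nm, " must have one value per age group")
    if (any(!is.finite(v)) || any(v < 0)) stop(nm, " must be finite and >= 0")
  }
  if (any(spec$prevalence_by_age > 1)) stop("prevalence must be in [0, 1]")
  if (spec$dm2_death_fraction < 0 || spec$dm2_death_fraction > 1)
    stop("dm2_death_fraction must be in [0, 1]")
  if (spec$followup_years <= 0) stop("followup_years must be positive")
  if (spec$weight_dispersion < 0) stop("weight_dispersion must be >= 0")
  if (spec$sex_ratio <= 0 || spec$sex_ratio >= 1)
    stop("sex_ratio must be in (0, 1)")
  invisible(spec)
}

# Schedule lookup with the open group extended beyond the grid.
schedule_at_age <- function(age, grid, values) {
  idx <- findInterval(age, grid$age_start)
  idx[idx == 0L] <- 1L
  values[idx]
}

#' Generate a synthetic longitudinal cohort
#'
#' Simulates one subject record per row: baseline age drawn from a
#' geometrically thinning elderly age pyramid, lognormal sampling weights
#' normalized to mean 1, baseline diabetes assigned by the age-specific
#' prevalence schedule (with the diagnosis age of prevalent cases imputed
#' uniformly between 30 and the baseline age, honoring the type-2 filter
#' that discards diagnoses before age 30), and mortality follow-up simulated
#' as a piecewise-exponential illness-death process: diabetes-free subjects
#' are exposed to the diagnosis hazard and to baseline mortality, diabetic
#' subjects to baseline mortality times the diabetes hazard ratio. Deaths of
#' diabetic subjects are certified to diabetes with probability
#' `dm2_death_fraction`; all other deaths are certified to other causes.
#'
#' @param spec a [cohort_spec()].
#' @return A data frame of class `synthetic_cohort` with one row per subject
#'   and columns `id`, `weight`, `sex`, `age_at_baseline`,
#'   `diabetic_at_baseline`, `age_at_diagnosis`, `incident_diagnosis_age`,
#'   `died`, `age_at_death`, `cause_of_death`. The generating spec is kept
#'   in the `"spec"` attribute for parameter-recovery work.
#' @examples
#' ch <- generate_cohort(cohort_spec(n_subjects = 500, seed = 7))
#' table(ch$diabetic_at_baseline)
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) spec <- do.call(cohort_spec, spec)
  validate_cohort_spec(spec)
  with_seed(spec$seed, {
    n <- as.integer(spec$n_subjects)
    a_min <- spec$age_range[1]; a_max <- spec$age_range[2]
    # age pyramid thinning at ~8%/year of age
    age <- a_min + stats::rexp(n, rate = 0.08)
    age <- pmin(age, a_max)
    sex <- ifelse(stats::runif(n) < spec$sex_ratio, "female", "male")
    w <- if (spec$weight_dispersion > 0) {
      stats::rlnorm(n, meanlog = 0, sdlog = spec$weight_dispersion)
    } else rep(1, n)
    w <- w / mean(w)
    prev <- schedule_at_age(age, spec$grid, spec$prevalence_by_age)
    diab0 <- stats::runif(n) < prev
    diag_age <- rep(NA_real_, n)
    diag_age[diab0] <- stats::runif(sum(diab0), 30, age[diab0])

    fu <- simulate_followup(
      age0 = age, diabetic0 = diab0, grid = spec$grid,
      incidence = spec$incidence_by_age,
      mortality_nd = spec$baseline_mortality_by_age,
      mortality_d = spec$baseline_mortality_by_age * spec$hr_diabetes_mortality,
      followup_years = spec$followup_years,
      dm2_death_fraction = spec$dm2_death_fraction
    )

    cohort <- data.frame(
      id = seq_len(n),
      weight = w,
      sex = sex,
      age_at_baseline = age,
      diabetic_at_baseline = diab0,
      age_at_diagnosis = ifelse(diab0, diag_age, fu$incident_diagnosis_age),
      incident_diagnosis_age = fu$incident_diagnosis_age,
      died = fu$died,
      age_at_death = fu$age_at_death,
      cause_of_death = fu$cause_of_death,
      stringsAsFactors = FALSE
    )
    attr(cohort, "spec") <- spec
    attr(cohort, "baseline_year") <- spec$baseline_year
    class(cohort) <- c("synthetic_cohort", "data.frame")
    cohort
  })
}

# Piecewise-exponential illness-death follow-up, vectorized over subjects.
# Hazards are constant within grid bins; the open bin extends upward.
simulate_followup <- function(age0, diabetic0, grid, incidence,
                              mortality_nd, mortality_d,
                              followup_years, dm2_death_fraction) {
  n <- length(age0)
  cur_age <- age0
  end_age <- age0 + followup_years
  diabetic <- diabetic0
  died <- rep(FALSE, n)
  age_at_death <- rep(NA_real_, n)
  cause <- rep(NA_character_, n)
  incident_diag <- rep(NA_real_, n)
  active <- rep(TRUE, n)
  bounds <- c(grid$age_start, Inf)

  while (any(active)) {
    i <- which(active)
    a <- cur_age[i]
    # next hazard changepoint or end of follow-up
    nxt <- bounds[findInterval(a, bounds) + 1L]
    seg_end <- pmin(nxt, end_age[i])
    h_inc <- ifelse(diabetic[i], 0,
                    schedule_at_age(a, grid, incidence))
    h_mor <- ifelse(diabetic[i],
                    schedule_at_age(a, grid, mortality_d),
                    schedule_at_age(a, grid, mortality_nd))
    h_tot <- h_inc + h_mor
    # exponential waiting time within the constant-hazard segment
    wait <- ifelse(h_tot > 0, stats::rexp(length(i)) / h_tot, Inf)
    event <- a + wait < seg_end
    t_event <- a + wait
    is_death <- event & (stats::runif(length(i)) * h_tot < h_mor)
    is_diag <- event & !is_death

    ii <- i[is_death]
    died[ii] <- TRUE
    age_at_death[ii] <- t_event[is_death]
    dm_flag <- diabetic[ii] &
      (stats::runif(length(ii)) < dm2_death_fraction)
    cause[ii] <- ifelse(dm_flag, "diabetes", "other")
    active[ii] <- FALSE

    ii <- i[is_diag]
    diabetic[ii] <- TRUE
    incident_diag[ii] <- t_event[is_diag]
    cur_age[ii] <- t_event[is_diag]

    ii <- i[!event]
    cur_age[ii] <- seg_end[!event]
    active[i[!event & seg_end >= end_age[i] - 1e-12]] <- FALSE
  }
  list(died = died, age_at_death = age_at_death, cause_of_death = cause,
       incident_diagnosis_age = incident_diag)
}

#' Specification of a synthetic mortality surface
#'
#' Ground truth for [generate_mortality_surface()]: a log-bilinear age-period
#' mortality model \eqn{\log m(x,t) = a_x + b_x k_t + \epsilon} in which the
#' period index \eqn{k_t} follows a random walk with drift. A companion table
#' gives the fraction of deaths attributed to diabetes per age group
#' (zero below age 30), used downstream for cause-deleted life tables.
#'
#' @param grid [age_grid()] for the surface rows (default full 0-4 ... 95+).
#' @param years calendar years of the surface columns (default 1980-2010).
#' @param true_ax per-age log-rate level.
#' @param true_bx per-age sensitivity to the period index; must sum to 1.
#' @param true_drift per-year drift of the period index.
#' @param sigma_kt innovation standard deviation of the period random walk.
#' @param sigma_eps standard deviation of the log-rate observation noise.
#' @param diabetes_fraction_by_age fraction of deaths attributed to diabetes
#'   per age group, in `[0, 1)` and zero below 30.
#' @param seed integer seed.
#' @return A list of class `surface_spec`.
#' @export
surface_spec <- function(grid = age_grid(0, 95),
                         years = 1980:2010,
                         true_ax = NULL,
                         true_bx = NULL,
                         true_drift = -0.5,
                         sigma_kt = 0.4,
                         sigma_eps = 0.01,
                         diabetes_fraction_by_age = NULL,
                         seed = 1L) {
  k <- nrow(grid)
  if (is.null(true_ax)) true_ax <- default_ax(grid)
  if (is.null(true_bx)) {
    raw <- exp(-0.12 * seq_len(k)) + 0.05
    true_bx <- raw / sum(raw)
  }
  if (is.null(diabetes_fraction_by_age))
    diabetes_fraction_by_age <- default_dm2_fraction(grid)
  spec <- list(grid = grid, years = years, true_ax = true_ax,
               true_bx = true_bx, true_drift = true_drift,
               sigma_kt = sigma_kt, sigma_eps = sigma_eps,
               diabetes_fraction_by_age = diabetes_fraction_by_age,
               seed = seed)
  validate_surface_spec(spec)
  class(spec) <- "surface_spec"
  spec
}

validate_surface_spec <- function(spec) {
  stopifnot_grid(spec$grid)
  k <- nrow(spec$grid)
  if (length(spec$years) < 1L) stop("years must be non-empty")
  if (length(spec$true_ax) != k || length(spec$true_bx) != k)
    stop("true_ax and true_bx must have one value per age group")
  if (abs(sum(spec$true_bx) - 1) > 1e-8)
    stop("true_bx must sum to 1 (|sum - 1| <= 1e-8)")
  if (spec$sigma_kt < 0 || spec$sigma_eps < 0)
    stop("innovation/noise scales must be >= 0")
  f <- spec$diabetes_fraction_by_age
  if (length(f) != k) stop("diabetes_fraction_by_age must match the grid")
  if (any(f < 0) || any(f >= 1))
    stop("diabetes_fraction_by_age must lie in [0, 1)")
  if (any(f[spec$grid$age_start < 30] != 0))
    stop("diabetes_fraction_by_age must be 0 below age 30")
  invisible(spec)
}

# Typical log central death rates for a middle-income population, used as
# the default a_x level; 5-year groups from 0-4 to 95+.
default_ax <- function(grid) {
  ages <- grid$age_start
  m <- ifelse(ages < 5, 0.006,
       ifelse(ages < 10, 5e-4,
       ifelse(ages < 15, 4e-4,
       ifelse(ages < 30, 0.0010 + 2e-5 * (ages - 15),
       0.0016 * exp(0.078 * (ages - 30))))))
  log(m)
}

default_dm2_fraction <- function(grid) {
  ages <- grid$age_start
  ifelse(ages < 30, 0,
  ifelse(ages < 60, 0.005 + 0.0005 * (ages - 30),
         pmin(0.06, 0.04 + 0.001 * (ages - 60))))
}

#' Generate a synthetic age-by-year mortality surface
#'
#' Realizes the log-bilinear model of a [surface_spec()]: the period index is
#' simulated as a random walk with drift started at 0, recentred to sum to
#' zero (absorbing the recentring into the level so that the realized
#' decomposition satisfies the usual identifiability constraints), and the
#' log rates receive i.i.d. Gaussian observation noise.
#'
#' @param spec a [surface_spec()].
#' @return A [mortality_surface()] whose `"truth"` attribute records the
#'   realized `ax`, `bx`, `kt`, the drift, and the diabetes death-fraction
#'   table, for parameter-recovery tests.
#' @export
generate_mortality_surface <- function(spec) {
  if (!inherits(spec, "surface_spec")) spec <- do.call(surface_spec, spec)
  validate_surface_spec(spec)
  with_seed(spec$seed, {
    ny <- length(spec$years)
    innov <- if (ny > 1)
      stats::rnorm(ny - 1, mean = spec$true_drift, sd = spec$sigma_kt)
    else numeric(0)
    kt <- cumsum(c(0, innov))
    ax <- spec$true_ax + spec$true_bx * mean(kt)
    kt <- kt - mean(kt)
    logm <- outer(spec$true_bx, kt) + ax
    if (spec$sigma_eps > 0)
      logm <- logm + matrix(stats::rnorm(length(logm), 0, spec$sigma_eps),
                            nrow = nrow(logm))
    surf <- mortality_surface(exp(logm), spec$grid, spec$years)
    attr(surf, "truth") <- list(
      ax = ax, bx = spec$true_bx, kt = kt, drift = spec$true_drift,
      sigma_kt = spec$sigma_kt,
      diabetes_fraction_by_age = spec$diabetes_fraction_by_age
    )
    surf
  })
}

#' Generate national population counts by age group
#'
#' @param grid an [age_grid()].
#' @param totals_by_age non-negative counts per age group.
#' @param year calendar year the counts refer to.
#' @return A data frame with columns `year`, `age_start`, `n_total`,
#'   compatible with [population_state()].
#' @export
generate_population_counts <- function(grid, totals_by_age, year) {
  stopifnot_grid(grid)
  if (length(totals_by_age) != nrow(grid))
    stop("totals_by_age must have one value per age group")
  if (any(totals_by_age < 0)) stop("population counts must be >= 0")
  data.frame(year = year, age_start = grid$age_start,
             n_total = as.numeric(totals_by_age))
}

#' Default coefficient sets for synthetic healthcare utilization
#'
#' Coefficients of the two-part generating model for annual utilization
#' counts: a logistic participation part and a log-linear intensity part,
#' each with an intercept, a diabetic indicator, and indicators for the
#' 70-79 and 80+ age bands. Magnitudes are chosen so that hospitalization
#' is rare (roughly one admission in ten person-years among non-diabetic
#' sexagenarians) while outpatient consultation is near-universal with a
#' handful of visits per user-year, and diabetic subjects use more of both.
#'
#' @param service `"hospitalization"` or `"outpatient"`.
#' @return list with elements `participation` and `intensity`, named numeric
#'   vectors `(intercept, diabetic, age70, age80)`.
#' @export
utilization_coefs <- function(service = c("hospitalization", "outpatient")) {
  service <- match.arg(service)
  if (service == "hospitalization") {
    list(
      participation = c(intercept = -2.3, diabetic = 0.65,
                        age70 = 0.35, age80 = 0.75),
      intensity = c(intercept = -1.1, diabetic = 0.35,
                    age70 = 0.10, age80 = 0.20)
    )
  } else {
    list(
      participation = c(intercept = 1.4, diabetic = 0.70,
                        age70 = 0.10, age80 = 0.15),
      intensity = c(intercept = 1.10, diabetic = 0.25,
                    age70 = 0.05, age80 = 0.10)
    )
  }
}

utilization_design <- function(cohort) {
  cbind(intercept = 1,
        diabetic = as.numeric(cohort$diabetic_at_baseline),
        age70 = as.numeric(cohort$age_at_baseline >= 70 &
                             cohort$age_at_baseline < 80),
        age80 = as.numeric(cohort$age_at_baseline >= 80))
}

#' Simulate annual healthcare-utilization counts for a cohort
#'
#' Draws annual counts from the two-part generating model: a Bernoulli
#' participation indicator with logistic linear predictor, times
#' `1 + Poisson(mu)` episodes where `log mu` is the intensity linear
#' predictor (so every user has at least one episode).
#'
#' @param cohort a [generate_cohort()] result.
#' @param participation_coefs,intensity_coefs named vectors
#'   `(intercept, diabetic, age70, age80)`; defaults from
#'   [utilization_coefs()] for the given service.
#' @param service which count column to fill: `"hospitalization"` fills
#'   `hospitalizations`, `"outpatient"` fills `outpatient_visits`.
#' @param seed integer seed.
#' @return The cohort with the utilization column added; the coefficients
#'   used are appended to the `"utilization_truth"` attribute.
#' @export
generate_utilization <- function(cohort,
                                 participation_coefs = NULL,
                                 intensity_coefs = NULL,
                                 service = c("hospitalization", "outpatient"),
                                 seed = 1L) {
  service <- match.arg(service)
  defaults <- utilization_coefs(service)
  participation_coefs <- participation_coefs %||% defaults$participation
  intensity_coefs <- intensity_coefs %||% defaults$intensity
  need <- c("intercept", "diabetic", "age70", "age80")
  for (v in list(participation_coefs, intensity_coefs))
    if (!all(need %in% names(v)))
      stop("coefficient vectors need components: ",
           paste(need, collapse = ", "))
  X <- utilization_design(cohort)
  with_seed(seed, {
    p <- stats::plogis(drop(X %*% participation_coefs[need]))
    mu <- exp(drop(X %*% intensity_coefs[need]))
    use <- stats::rbinom(nrow(X), 1L, p)
    count <- use * (1L + stats::rpois(nrow(X), mu))
    col <- if (service == "hospitalization") "hospitalizations"
           else "outpatient_visits"
    cohort[[col]] <- count
    tr <- attr(cohort, "utilization_truth") %||% list()
    tr[[service]] <- list(participation = participation_coefs[need],
                          intensity = intensity_coefs[need])
    attr(cohort, "utilization_truth") <- tr
    cohort
  })
}

#' Write / read a synthetic cohort as CSV with a YAML sidecar
#'
#' The CSV holds one row per subject; the sidecar (same path with extension
#' `.yml`) stores the generating parameters so recovery tests can be run
#' against files alone.
#'
#' @param cohort a `synthetic_cohort`.
#' @param path CSV file path.
#' @return `write_cohort_csv` returns `path` invisibly; `read_cohort_csv`
#'   returns the cohort with the spec restored when the sidecar is present.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE)
  spec <- attr(cohort, "spec")
  if (!is.null(spec)) {
    side <- sub("\\.csv$", ".yml", path)
    sp <- unclass(spec)
    sp$grid <- list(start = spec$grid$age_start[1],
                    open_start = spec$grid$age_start[nrow(spec$grid)],
                    width = spec$grid$age_width[1])
    yaml::write_yaml(sp, side)
  }
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  cohort <- utils::read.csv(path, stringsAsFactors = FALSE)
  side <- sub("\\.csv$", ".yml", path)
  if (file.exists(side)) {
    sp <- yaml::read_yaml(side)
    g <- sp$grid
    sp$grid <- age_grid(g$start, g$open_start, g$width)
    for (nm in c("prevalence_by_age", "incidence_by_age",
                 "baseline_mortality_by_age"))
      sp[[nm]] <- as.numeric(sp[[nm]])
    sp$age_range <- as.numeric(sp$age_range)
    class(sp) <- "cohort_spec"
    attr(cohort, "spec") <- sp
    attr(cohort, "baseline_year") <- sp$baseline_year
  }
  class(cohort) <- c("synthetic_cohort", "data.frame")
  cohort
}
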
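test_that("cohort generation is reproducible and honors the spec", {
  sp <- cohort_spec(n_subjects = 400, seed = 11)
  a <- generate_cohort(sp)
  b <- generate_cohort(sp)
  expect_identical(a, b)
  expect_equal(nrow(a), 400L)
  # sample size matches the requested survey size exactly
  expect_equal(nrow(generate_cohort(cohort_spec(n_subjects = 2827,
                                                seed = 1))), 2827L)
  expect_true(all(a$weight > 0))
  expect_equal(mean(a$weight), 1)
  expect_true(all(a$age_at_diagnosis >= 30, na.rm = TRUE))
  expect_true(all(a$age_at_death[a$died] > a$age_at_baseline[a$died]))
  expect_true(all(!is.na(a$cause_of_death[a$died])))
  expect_true(all(is.na(a$cause_of_death[!a$died])))
})

test_that("forced prevalence of one makes every subject a prevalent case", {
  sp <- cohort_spec(n_subjects = 200, prevalence_by_age = rep(1, 8),
                    seed = 2)
  ch <- generate_cohort(sp)
  expect_true(all(ch$diabetic_at_baseline))
  expect_true(all(ch$age_at_diagnosis >= 30 &
                    ch$age_at_diagnosis <= ch$age_at_baseline))
})

test_that("spec validation rejects malformed inputs", {
  expect_error(cohort_spec(n_subjects = 0), "positive")
  expect_error(cohort_spec(hr_diabetes_mortality = 0), "> 0")
  expect_error(cohort_spec(prevalence_by_age = rep(1.2, 8)), "\\[0, 1\\]")
  expect_error(cohort_spec(incidence_by_age = rep(-1, 8)), ">= 0")
})

test_that("unit hazard ratio equalizes death risk across strata", {
  # with hr = 1 the exponential mortality model is identical for diabetic
  # and non-diabetic subjects; oracle: direct binomial simulation of the
  # same constant-hazard model
  m <- 0.05
  sp <- cohort_spec(n_subjects = 20000, hr_diabetes_mortality = 1,
                    prevalence_by_age = rep(0.5, 8),
                    incidence_by_age = rep(0, 8),
                    baseline_mortality_by_age = rep(m, 8),
                    followup_years = 5, weight_dispersion = 0, seed = 3)
  ch <- generate_cohort(sp)
  p_d <- mean(ch$died[ch$diabetic_at_baseline])
  p_nd <- mean(ch$died[!ch$diabetic_at_baseline])
  p_true <- 1 - exp(-5 * m)   # closed form for the constant hazard
  se <- sqrt(p_true * (1 - p_true) / (nrow(ch) / 2))
  expect_lt(abs(p_d - p_nd), 3 * sqrt(2) * se)
  expect_lt(abs(p_d - p_true), 3 * se)
  expect_lt(abs(p_nd - p_true), 3 * se)
})

test_that("empirical prevalence converges to the generating schedule", {
  sp <- cohort_spec(n_subjects = 50000, seed = 17)
  ch <- generate_cohort(sp)
  est <- estimate_prevalence(ch, sp$grid)
  idx <- age_group_index(ch$age_at_baseline, sp$grid)
  for (g in seq_len(nrow(sp$grid))) {
    w <- ch$weight[idx == g]
    n_eff <- sum(w)^2 / sum(w^2)
    p <- sp$prevalence_by_age[g]
    se <- sqrt(p * (1 - p) / n_eff)
    expect_lt(abs(est$prevalence[g] - p), 3 * se)
  }
})

test_that("mortality surface realizes the log-bilinear model", {
  g <- age_grid(0, 95)
  # no dynamics: constant surface at exp(ax)
  sp0 <- surface_spec(grid = g, true_drift = 0, sigma_kt = 0,
                      sigma_eps = 0, seed = 5)
  s0 <- generate_mortality_surface(sp0)
  expect_equal(ncol(s0$m), 31L)   # 1980-2010 inclusive
  expect_true(all(abs(s0$m - s0$m[, 1]) < 1e-12))
  expect_equal(unname(log(s0$m[, 1])), sp0$true_ax)

  # pure drift: log m declines linearly with slope drift * bx
  spd <- surface_spec(grid = g, true_drift = -0.5, sigma_kt = 0,
                      sigma_eps = 0, seed = 5)
  sd_ <- generate_mortality_surface(spd)
  slopes <- (log(sd_$m[, 31]) - log(sd_$m[, 1])) / 30
  expect_equal(unname(slopes), -0.5 * spd$true_bx, tolerance = 1e-10)

  expect_identical(generate_mortality_surface(spd)$m, sd_$m)
  expect_error(surface_spec(grid = g, true_bx = rep(1, nrow(g))),
               "sum to 1")
  bad_f <- rep(0.5, nrow(g))
  expect_error(surface_spec(grid = g, diabetes_fraction_by_age = bad_f),
               "0 below age 30")
})

test_that("population count generation validates and sums", {
  g <- age_grid(60, 95)
  z <- generate_population_counts(g, rep(0, 8), 2006)
  expect_equal(sum(z$n_total), 0)
  one <- generate_population_counts(g, c(1000, rep(0, 7)), 2006)
  expect_equal(one$n_total[1], 1000)
  expect_error(generate_population_counts(g, rep(-1, 8), 2006), ">= 0")
  # an elderly share of 13% of a 5.1-million population
  elderly <- 0.13 * 5.1e6
  prof <- exp(-0.08 * (g$age_start - 60)); prof <- prof / sum(prof)
  tab <- generate_population_counts(g, elderly * prof, 2006)
  expect_equal(sum(tab$n_total), 663000)
})

test_that("utilization counts follow the two-part generating model", {
  ch <- generate_cohort(cohort_spec(n_subjects = 20000, seed = 23,
                                    weight_dispersion = 0))
  # participation forced to zero: no use at all
  none <- generate_utilization(ch, participation_coefs =
      c(intercept = -50, diabetic = 0, age70 = 0, age80 = 0),
      service = "hospitalization", seed = 4)
  expect_true(all(none$hospitalizations == 0))
  # participation one, constant intensity c: mean count -> 1 + c
  cc <- 0.7
  all_use <- generate_utilization(ch, participation_coefs =
      c(intercept = 50, diabetic = 0, age70 = 0, age80 = 0),
      intensity_coefs = c(intercept = log(cc), diabetic = 0,
                          age70 = 0, age80 = 0),
      service = "hospitalization", seed = 4)
  se <- sqrt(cc / nrow(ch))
  expect_lt(abs(mean(all_use$hospitalizations) - (1 + cc)), 4 * se)
  # positive diabetic coefficient: diabetic stratum uses more care
  dm <- generate_utilization(ch, service = "outpatient", seed = 4)
  expect_gt(mean(dm$outpatient_visits[dm$diabetic_at_baseline]),
            mean(dm$outpatient_visits[!dm$diabetic_at_baseline]))
})

test_that("cohort and surface round-trip through CSV", {
  tmp <- withr::local_tempdir()
  ch <- generate_cohort(cohort_spec(n_subjects = 50, seed = 9))
  f <- file.path(tmp, "cohort.csv")
  write_cohort_csv(ch, f)
  back <- read_cohort_csv(f)
  expect_equal(back$age_at_baseline, ch$age_at_baseline)
  expect_equal(attr(back, "spec")$prevalence_by_age,
               attr(ch, "spec")$prevalence_by_age)
  s <- generate_mortality_surface(surface_spec(seed = 2))
  fs <- file.path(tmp, "surface.csv")
  write_surface_csv(s, fs)
  s2 <- read_surface_csv(fs)
  expect_equal(s2$m, s$m, ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(s2$years, s$years)
})
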
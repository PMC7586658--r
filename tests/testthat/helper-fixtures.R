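# Shared fixtures: small deterministic objects built in code.

grid60 <- age_grid(60, 95)
grid30 <- age_grid(30, 95)

# Minimal hand-checkable cohort: columns required by the rate estimators.
toy_cohort <- function(age, diabetic, weight = 1, diag_age = NA_real_,
                       incident_age = NA_real_, died = FALSE,
                       death_age = NA_real_, cause = NA_character_,
                       followup = 12) {
  n <- length(age)
  ch <- data.frame(
    id = seq_len(n),
    weight = rep_len(weight, n),
    sex = "female",
    age_at_baseline = age,
    diabetic_at_baseline = rep_len(diabetic, n),
    age_at_diagnosis = rep_len(diag_age, n),
    incident_diagnosis_age = rep_len(incident_age, n),
    died = rep_len(died, n),
    age_at_death = rep_len(death_age, n),
    cause_of_death = rep_len(cause, n),
    stringsAsFactors = FALSE
  )
  attr(ch, "spec") <- list(followup_years = followup)
  class(ch) <- c("synthetic_cohort", "data.frame")
  ch
}

# Constant totals series over a set of years.
flat_totals <- function(grid, years, per_group = 1000) {
  do.call(rbind, lapply(years, function(y)
    data.frame(year = y, age_start = grid$age_start,
               n_total = rep_len(per_group, nrow(grid)))))
}

# Single-year numerical survival integration for a smooth hazard mu(a):
# the independent oracle for abridged life-table accuracy.
e_numeric <- function(mu, from = 60, upper = 130, dt = 0.01) {
  a <- seq(from, upper, by = dt)
  H <- cumsum(mu(a)) * dt            # left-Riemann cumulative hazard
  S <- exp(-c(0, H[-length(H)]))
  sum(S) * dt + S[length(S)] / mu(upper)   # exponential tail closure
}

# Group central death rates consistent with hazard mu on an age grid:
# m_g = integral(mu * S) / integral(S) over the group.
group_mx_from_hazard <- function(mu, grid, from = grid$age_start[1],
                                 upper = 130, dt = 0.01) {
  a <- seq(from, upper, by = dt)
  H <- cumsum(mu(a)) * dt
  S <- exp(-c(0, H[-length(H)]))
  vapply(seq_len(nrow(grid)), function(g) {
    lo <- grid$age_start[g]
    hi <- min(grid$age_start[g] + grid$age_width[g], upper)
    sel <- a >= lo & a < hi
    sum(mu(a[sel]) * S[sel]) / sum(S[sel])
  }, numeric(1))
}
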
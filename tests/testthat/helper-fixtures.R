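# shared fixtures: small in-code series and cohorts

flat_series <- function(scr = 0.8, times = seq(0, 240, by = 24)) {
  lab_series(times, rep(scr, length(times)))
}

# random series for oracle comparisons: modest lengths, values coarse enough
# to produce threshold hits and ties
random_series <- function(n_points, rng_values = seq(0.4, 2.4, by = 0.1)) {
  times <- sort(runif(n_points, 0, 200))
  lab_series(times, sample(rng_values, n_points, replace = TRUE))
}

# brute-force KDIGO detection: check every ordered measurement pair against
# both criteria, independent of the rolling-minimum implementation
oracle_detect <- function(series) {
  t <- series$time; s <- series$scr
  for (j in seq_along(t)) {
    for (i in seq_len(j)) {
      in48 <- t[i] > t[j] - 48 && t[i] <= t[j]
      in7d <- t[i] > t[j] - 168 && t[i] <= t[j]
      if ((in48 && s[j] - s[i] >= 0.3 - 1e-9) ||
          (in7d && s[j] >= 1.5 * s[i] - 1e-9 && s[j] > s[i])) {
        return(t[j])
      }
    }
  }
  NA_real_
}

small_cohort <- function(n = 150, incidence = 0.3, seed = 11, ...) {
  generate_cohort(generator_config(n_admissions = n, aki_incidence = incidence,
                                   seed = seed, ...))
}

series_of <- function(cohort, pid) {
  lb <- cohort$labs[cohort$labs$patient_id == pid, ]
  lab_series(lb$time, lb$scr)
}

events_of <- function(cohort, pid) {
  cohort$events[cohort$events$patient_id == pid, , drop = FALSE]
}

full_context <- function() {
  list(bed = "12", ward = "nephrology", admit_date = "2021-03-01",
       scr = 1.544, test_date = "2021-03-04", phone = "8100")
}
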
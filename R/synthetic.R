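# Synthetic inpatient EHR generator: admissions, creatinine trajectories with
# injectable KDIGO-consistent AKI episodes, death/dialysis events, and
# arm-dependent care-process events, with per-patient reproducible substreams.

#' Configuration for the synthetic EHR generator
#'
#' Defaults emulate the marginal rates of a large inpatient alert trial:
#' ~1.4 AKI episodes per 100 admissions, stage mix 50/25/25% for stages
#' 1/2/3, baseline creatinine log-normal around 0.87 mg/dL, ~11% death and
#' ~12% dialysis within 7 days of randomization among AKI patients, and
#' per-arm care-process rates taken from the trial's observed usual-care and
#' alert-arm proportions. Setting both members of every care-effect pair
#' equal yields a null configuration.
#'
#' @param n_admissions number of admissions to simulate (>= 1).
#' @param aki_incidence probability an admission receives an injected AKI
#'   episode (default 0.014).
#' @param stage_mix length-3 probability vector over injected stages 1/2/3
#'   (must sum to 1; default `c(0.50, 0.25, 0.25)`).
#' @param baseline_scr_meanlog,baseline_scr_sdlog log-normal parameters of
#'   baseline creatinine in mg/dL (defaults `log(0.87)` and 0.39, matching a
#'   median of 0.87 with IQR roughly 0.70-1.18).
#' @param scr_cv multiplicative measurement/biological noise CV on the
#'   log scale (default 0.05). Noise is clamped per patient so that a
#'   non-AKI series can never satisfy either KDIGO criterion.
#' @param ward_interval_hours nominal lab-draw interval on wards (default 24).
#' @param icu_interval_hours range of draw intervals in ICU (default
#'   `c(6, 12)`).
#' @param mortality_7d,mortality_28d,mortality_90d cumulative death
#'   probabilities within 7/28/90 days of randomization for AKI patients
#'   (defaults 0.11, 0.35, 0.38); the 7-day component is modulated by stage
#'   (x0.6 / x1.0 / x1.8 for stages 1/2/3).
#' @param dialysis_7d marginal 7-day dialysis probability for AKI patients
#'   (default 0.12); dialysis is simulated only for stage-3 episodes, at the
#'   conditional rate `dialysis_7d / stage_mix[3]`.
#' @param p_icu,p_medical,p_male admission mix probabilities (defaults 0.606,
#'   0.44, 0.707).
#' @param age_mean,age_sd age distribution (normal, truncated to
#'   `[18, 95]`; defaults 63 and 13).
#' @param los_meanlog,los_sdlog log-normal length-of-stay parameters in
#'   hours (defaults `log(180)` and 0.7; AKI admissions are extended to cover
#'   onset plus follow-up).
#' @param arm_effects named list of care-process probabilities; see
#'   [default_arm_effects()]. Each 2-day element is `c(usual, alert)`;
#'   nephrotoxins carry `c(usual_3d, usual_7d, alert_3d, alert_7d)`.
#' @param base_seed randomization seed scheme passed to [randomize()]
#'   (default 20180101).
#' @param seed global generator seed; per-patient substreams are derived from
#'   it by counter so results do not depend on iteration order.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_admissions,
                             aki_incidence = 0.014,
                             stage_mix = c(0.50, 0.25, 0.25),
                             baseline_scr_meanlog = log(0.87),
                             baseline_scr_sdlog = 0.39,
                             scr_cv = 0.05,
                             ward_interval_hours = 24,
                             icu_interval_hours = c(6, 12),
                             mortality_7d = 0.11,
                             mortality_28d = 0.35,
                             mortality_90d = 0.38,
                             dialysis_7d = 0.12,
                             p_icu = 0.606,
                             p_medical = 0.44,
                             p_male = 0.707,
                             age_mean = 63, age_sd = 13,
                             los_meanlog = log(180), los_sdlog = 0.7,
                             arm_effects = default_arm_effects(),
                             base_seed = 20180101,
                             seed = 1L) {
  if (n_admissions < 1) stop("n_admissions must be >= 1", call. = FALSE)
  probs <- c(aki_incidence, stage_mix, mortality_7d, mortality_28d,
             mortality_90d, dialysis_7d, p_icu, p_medical, p_male)
  if (any(probs < 0 | probs > 1)) {
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (length(stage_mix) != 3 || abs(sum(stage_mix) - 1) > 1e-8) {
    stop("stage_mix must be a 3-vector summing to 1", call. = FALSE)
  }
  if (mortality_7d > mortality_28d || mortality_28d > mortality_90d) {
    stop("cumulative mortality must be nondecreasing over 7/28/90 days",
         call. = FALSE)
  }
  structure(as.list(environment()), class = "generator_config")
}

#' Default per-arm care-process probabilities
#'
#' Usual-care and alert-arm probabilities for the care-centered outcomes,
#' matching the observed rates of the reference trial arms. Two-day process
#' flags are `c(usual, alert)`; nephrotoxin exposures are
#' `c(usual_3d, usual_7d, alert_3d, alert_7d)` with the 7-day value never
#' below the 3-day one.
#'
#' @return Named list of probability vectors.
#' @export
default_arm_effects <- function() {
  list(
    iv_fluids = c(0.618, 0.826),
    urinalysis = c(0.130, 0.362),
    fluid_io = c(0.685, 0.886),
    scr_measured = c(0.750, 0.925),
    ultrasound = c(0.006, 0.053),
    nephrology_consult = c(0.205, 0.234),
    anemia_corrected = c(0.232, 0.460),
    aki_documented = c(0.273, 0.499),
    contrast = c(0.030, 0.045, 0.028, 0.047),
    aminoglycoside = c(0.005, 0.007, 0.004, 0.006),
    vancomycin = c(0.024, 0.033, 0.023, 0.028),
    chemotherapy = c(0.016, 0.020, 0.015, 0.021),
    nsaid = c(0.110, 0.124, 0.050, 0.064),
    acei_arb = c(0.043, 0.051, 0.038, 0.045)
  )
}

# per-patient substream seed derived from the global seed by counter;
# kept inside 32-bit integer range
.substream_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(i) * 16807) %% 2147483629) + 1L
}

# clamp multiplicative noise so a flat series at baseline b can never meet
# either criterion: swing ratio < 1.5 and swing delta < 0.3 mg/dL
.noise_bound <- function(b) 0.9 * min(0.15 / b, 0.2)

#' Inject a KDIGO-consistent AKI episode into a creatinine series
#'
#' Rewrites the post-onset segment of a series as a piecewise log-linear rise
#' from the measured 7-day baseline to `ratio x baseline`, a plateau, and an
#' exponential partial recovery. A measurement is inserted at the peak so the
#' target stage is always observed. The peak is computed from the *measured*
#' pre-onset minimum, so detection and staging by the KDIGO engine reproduce
#' the requested stage exactly.
#'
#' @param series a [lab_series()] free of AKI (e.g. a generated non-AKI
#'   trajectory).
#' @param stage requested highest stage, 1, 2 or 3.
#' @param onset hours since admission; must fall strictly after the first
#'   measurement and before the last.
#' @param ratio peak-to-baseline ratio; defaults to a draw from the stage's
#'   band (1.55-1.88 / 2.05-2.85 / 3.1-4.8).
#' @param rise_hours,plateau_hours rise and plateau durations (defaults 48
#'   and 48).
#' @param recovery_ratio ratio the series decays toward after the plateau
#'   (default 1.2).
#' @return The modified [lab_series()], with attribute `"ratio"` set to the
#'   ratio used.
#' @export
inject_aki <- function(series, stage, onset, ratio = NULL,
                       rise_hours = 48, plateau_hours = 48,
                       recovery_ratio = 1.2) {
  stopifnot(inherits(series, "lab_series"), stage %in% 1:3)
  if (onset <= min(series$time) || onset > max(series$time)) {
    stop("onset must fall inside the admission, after the first measurement",
         call. = FALSE)
  }
  if (is.null(ratio)) {
    ratio <- switch(stage, stats::runif(1, 1.55, 1.88),
                    stats::runif(1, 2.05, 2.85), stats::runif(1, 3.1, 4.8))
  }
  if (rise_hours <= 0 || rise_hours >= 120) {
    stop("rise_hours must lie in (0, 120) so the baseline nadir stays inside ",
         "the 7-day window at the peak", call. = FALSE)
  }
  time <- series$time
  scr <- series$scr
  win_full <- time > onset - 168 & time <= onset
  if (!any(win_full)) stop("no baseline measurement within 7 days of onset",
                           call. = FALSE)
  base_meas <- min(scr[win_full])
  if (stage < 3 && ratio * base_meas >= 3.95) {
    stop("baseline too high for the requested stage: peak would cross the ",
         "4.0 mg/dL stage-3 rule", call. = FALSE)
  }
  t_peak <- onset + rise_hours
  # place the 7-day nadir where it is still inside the rolling window at the
  # peak, so the measured rise ratio at the peak equals `ratio` exactly
  win_recent <- time > t_peak - 168 & time <= onset
  if (!any(win_recent)) {
    time <- c(time, onset - 1)
    scr <- c(scr, base_meas)
  } else {
    j <- which(win_recent)[which.min(scr[win_recent])]
    scr[j] <- base_meas
  }
  ratio_at <- function(t) {
    ifelse(t <= onset, 1,
      ifelse(t <= t_peak, exp(log(ratio) * (t - onset) / rise_hours),
        ifelse(t <= t_peak + plateau_hours, ratio,
          recovery_ratio + (ratio - recovery_ratio) *
            exp(-(t - t_peak - plateau_hours) / 72))))
  }
  post <- time > onset
  scr[post] <- ratio_at(time[post]) * base_meas
  # guarantee the peak itself is observed
  if (!any(abs(time - t_peak) <= 1)) {
    time <- c(time, t_peak)
    scr <- c(scr, ratio * base_meas)
  }
  out <- lab_series(time, scr, series$admission_time)
  attr(out, "ratio") <- ratio
  out
}

# one admission's baseline (pre-AKI) trajectory
.baseline_trajectory <- function(b, los, icu, cfg) {
  interval <- if (icu) stats::runif(1, cfg$icu_interval_hours[1],
                                    cfg$icu_interval_hours[2])
              else cfg$ward_interval_hours
  t <- stats::runif(1, 1, min(interval, los))
  times <- c()
  while (t <= los) {
    times <- c(times, t)
    step <- if (icu) stats::runif(1, cfg$icu_interval_hours[1],
                                  cfg$icu_interval_hours[2])
            else interval * stats::runif(1, 0.8, 1.2)
    t <- t + step
  }
  if (!length(times)) times <- min(1, los)
  d <- .noise_bound(b)
  noise <- pmin(pmax(exp(stats::rnorm(length(times), 0, cfg$scr_cv)),
                     1 - d), 1 + d)
  lab_series(times, b * noise)
}

#' Generate a synthetic cohort of inpatient admissions
#'
#' Simulates `n_admissions` admissions with demographics, ward/ICU mix,
#' creatinine trajectories, injected AKI episodes at the configured incidence
#' and stage mix, stage-dependent death and dialysis, stratified seeded
#' randomization of detected episodes, and arm-dependent care-process events.
#' Every admission uses its own RNG substream derived from `config$seed` by
#' counter, so cohorts are reproducible and independent of iteration order.
#'
#' @param config a [generator_config()].
#' @return An object of class `synthetic_cohort`: a list with data frames
#'   `admissions`, `labs` (`patient_id`, `time` in hours, `scr` mg/dL),
#'   `events` (`patient_id`, `time`, `kind`, `value`), `ground_truth` (one
#'   row per admission: injected AKI flag, stage, onset, arm, event times)
#'   and the `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  cfg <- config
  n <- cfg$n_admissions
  study_start <- as.POSIXct("2019-08-01 00:00:00", tz = "UTC")

  adm_rows <- vector("list", n)
  lab_rows <- vector("list", n)
  ev_rows <- vector("list", n)
  gt_rows <- vector("list", n)

  for (i in seq_len(n)) {
    set.seed(.substream_seed(cfg$seed, i))
    pid <- sprintf("P%06d", i)
    age <- min(max(round(stats::rnorm(1, cfg$age_mean, cfg$age_sd)), 18), 95)
    sex <- if (stats::runif(1) < cfg$p_male) "male" else "female"
    icu <- stats::runif(1) < cfg$p_icu
    ward <- if (stats::runif(1) < cfg$p_medical) "medical" else "surgical"
    admit <- study_start + stats::runif(1, 0, 21000) * 3600
    b <- stats::rlnorm(1, cfg$baseline_scr_meanlog, cfg$baseline_scr_sdlog)
    b <- min(max(b, 0.3), 4.0)
    los <- max(stats::rlnorm(1, cfg$los_meanlog, cfg$los_sdlog), 12)
    aki <- stats::runif(1) < cfg$aki_incidence

    stage <- NA_integer_; onset <- NA_real_; ratio <- NA_real_
    death_time <- NA_real_; dialysis_time <- NA_real_
    if (aki) {
      stage <- sample.int(3L, 1L, prob = cfg$stage_mix)
      # keep stage-1/2 peaks clear of the 4.0 mg/dL stage-3 rule: cap the
      # baseline so the lower band edge is feasible, then draw the peak
      # ratio from the feasible part of the stage's band
      if (stage == 1L) b <- min(b, 2.3)
      if (stage == 2L) b <- min(b, 1.75)
      onset <- min(max(stats::rlnorm(1, log(6.5 * 24), 0.9), 30), 21 * 24)
      los <- max(los, onset + 168 + stats::runif(1, 24, 240))
    }

    series <- .baseline_trajectory(b, los, icu, cfg)
    detect_time <- NA_real_
    if (aki) {
      base_meas <- rolling_min(series, onset, 168)
      ratio <- switch(stage,
        stats::runif(1, 1.55, min(1.88, 3.9 / base_meas)),
        stats::runif(1, 2.05, min(2.85, 3.9 / base_meas)),
        stats::runif(1, 3.1, 4.8))
      series <- inject_aki(series, stage, onset, ratio = ratio)
      # stage-dependent death within 7 d of randomization, later deaths
      # after; early deaths are kept past the observed peak so the injected
      # stage is always reached before the series is truncated
      mort_mult <- c(0.6, 1.0, 1.8)[stage]
      u <- stats::runif(1)
      p7 <- cfg$mortality_7d * mort_mult
      if (u < p7) {
        death_time <- onset + stats::runif(1, 54, 160)
      } else if (u < p7 + (cfg$mortality_28d - cfg$mortality_7d)) {
        death_time <- onset + stats::runif(1, 169, 672)
      } else if (u < p7 + (cfg$mortality_90d - cfg$mortality_7d)) {
        death_time <- onset + stats::runif(1, 673, 2160)
      }
      if (stage == 3L && cfg$stage_mix[3] > 0) {
        p_dx <- min(cfg$dialysis_7d / cfg$stage_mix[3], 1)
        if (stats::runif(1) < p_dx) {
          dialysis_time <- onset + stats::runif(1, 6, 120)
          if (!is.na(death_time)) dialysis_time <- min(dialysis_time,
                                                       death_time - 1)
        }
      }
      if (!is.na(death_time)) {
        keep <- series$time <= death_time
        if (!any(keep)) keep[1] <- TRUE
        series <- lab_series(series$time[keep], series$scr[keep])
        if (death_time <= los) los <- death_time
      }
      # randomization is triggered by the alert at the first measurement
      # crossing a criterion (at or shortly after the injected onset)
      detect_time <- detect_aki(series)$onset_time
    }

    adm_rows[[i]] <- data.frame(
      patient_id = pid, admit_time = admit,
      discharge_time = admit + los * 3600,
      ward_type = ward, icu = icu, age = age, sex = sex,
      eskd_admission = FALSE, kidney_transplant = FALSE,
      repeat_admission = FALSE, stringsAsFactors = FALSE)
    lab_rows[[i]] <- data.frame(patient_id = pid, time = series$time,
                                scr = series$scr, stringsAsFactors = FALSE)
    evs <- list()
    if (!is.na(death_time)) {  # post-discharge deaths feed 28/90-day outcomes
      evs <- c(evs, list(data.frame(patient_id = pid, time = death_time,
                                    kind = "death", value = NA_real_)))
    }
    if (!is.na(dialysis_time)) {
      evs <- c(evs, list(data.frame(patient_id = pid, time = dialysis_time,
                                    kind = "dialysis_start", value = NA_real_)))
    }
    ev_rows[[i]] <- if (length(evs)) do.call(rbind, evs) else NULL
    gt_rows[[i]] <- data.frame(
      patient_id = pid, aki = aki, stage = stage, onset = onset,
      detect_time = detect_time, ratio = ratio, death_time = death_time,
      dialysis_time = dialysis_time, stringsAsFactors = FALSE)
  }

  admissions <- do.call(rbind, adm_rows)
  labs <- do.call(rbind, lab_rows)
  events <- do.call(rbind, ev_rows)
  if (is.null(events)) {
    events <- data.frame(patient_id = character(), time = numeric(),
                         kind = character(), value = numeric())
  }
  ground_truth <- do.call(rbind, gt_rows)

  cohort <- structure(
    list(admissions = admissions, labs = labs, events = events,
         ground_truth = ground_truth, config = cfg),
    class = "synthetic_cohort")
  .add_care_events(cohort)
}

# randomize detected episodes in enrolment order and draw arm-dependent care
# events for them
.add_care_events <- function(cohort) {
  cfg <- cohort$config
  gt <- cohort$ground_truth
  adm <- cohort$admissions
  aki_ids <- gt$patient_id[gt$aki]
  gt$arm <- NA_character_
  gt$rand_time <- NA_real_
  if (!length(aki_ids)) {
    cohort$ground_truth <- gt
    return(cohort)
  }
  # enrolment order is chronological by absolute alert (detection) time
  info <- merge(gt[gt$aki, c("patient_id", "detect_time", "stage",
                             "death_time")],
                adm[, c("patient_id", "admit_time", "ward_type", "icu",
                        "discharge_time")],
                by = "patient_id")
  info$alert_abs <- as.numeric(info$admit_time) + info$detect_time * 3600
  info$stratum <- paste(info$ward_type, ifelse(info$icu, "icu", "ward"),
                        sep = "_")
  info <- info[order(info$alert_abs), ]
  info$draw_index <- stats::ave(seq_len(nrow(info)), info$stratum,
                                FUN = seq_along)
  info$arm <- NA_character_
  for (s in unique(info$stratum)) {
    sel <- info$stratum == s
    info$arm[sel] <- randomize(s, info$draw_index[sel],
                               base_seed = cfg$base_seed)$arm
  }

  care_rows <- vector("list", nrow(info))
  for (j in seq_len(nrow(info))) {
    pid <- info$patient_id[j]
    i <- as.integer(sub("^P", "", pid))
    set.seed(.substream_seed(cfg$seed + 1000000L, i))
    armcol <- if (info$arm[j] == "alert") 2L else 1L
    r <- info$detect_time[j]
    dis <- (as.numeric(info$discharge_time[j]) -
              as.numeric(info$admit_time[j])) / 3600
    evs <- list()
    ae <- cfg$arm_effects
    for (k in c("iv_fluids", "urinalysis", "fluid_io", "scr_measured",
                "ultrasound", "nephrology_consult")) {
      if (stats::runif(1) < ae[[k]][armcol]) {
        evs <- c(evs, list(data.frame(patient_id = pid,
                                      time = r + stats::runif(1, 0.5, 48),
                                      kind = k, value = NA_real_)))
      }
    }
    # hemoglobin: corrected means a value strictly over 9.0 g/dL in window
    hb <- if (stats::runif(1) < ae$anemia_corrected[armcol]) {
      stats::runif(1, 9.5, 13.5)
    } else stats::runif(1, 6.5, 9.0)
    evs <- c(evs, list(data.frame(patient_id = pid,
                                  time = r + stats::runif(1, 0.5, 48),
                                  kind = "hemoglobin", value = hb)))
    for (k in c("contrast", "aminoglycoside", "vancomycin", "chemotherapy",
                "nsaid", "acei_arb")) {
      p3 <- ae[[k]][armcol * 2 - 1]
      p7 <- ae[[k]][armcol * 2]
      u <- stats::runif(1)
      if (u < p3) {
        evs <- c(evs, list(data.frame(patient_id = pid,
                                      time = r + stats::runif(1, 0.5, 72),
                                      kind = k, value = NA_real_)))
      } else if (u < p7) {
        evs <- c(evs, list(data.frame(patient_id = pid,
                                      time = r + stats::runif(1, 72.5, 168),
                                      kind = k, value = NA_real_)))
      }
    }
    if (stats::runif(1) < ae$aki_documented[armcol]) {
      evs <- c(evs, list(data.frame(patient_id = pid, time = dis,
                                    kind = "aki_documented", value = NA_real_)))
    }
    ev <- do.call(rbind, evs)
    if (!is.na(info$death_time[j])) {  # no care activity after death
      ev <- ev[ev$time <= info$death_time[j], , drop = FALSE]
    }
    care_rows[[j]] <- ev
  }
  care <- do.call(rbind, care_rows)
  cohort$events <- rbind(cohort$events, care)
  cohort$events <- cohort$events[order(cohort$events$patient_id,
                                       cohort$events$time), ]
  rownames(cohort$events) <- NULL

  gt$arm[match(info$patient_id, gt$patient_id)] <- info$arm
  gt$rand_time[match(info$patient_id, gt$patient_id)] <- info$detect_time
  cohort$ground_truth <- gt
  cohort
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d admissions, %d with injected AKI, %d lab rows\n",
              nrow(x$admissions), sum(x$ground_truth$aki), nrow(x$labs)))
  invisible(x)
}
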
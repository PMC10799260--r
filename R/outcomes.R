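# Trial outcome definitions: primary eGFR-change outcome (with the death -> 0
# imputation), secondary patient-centered outcomes, and care-centered process
# outcomes over the trial's time windows.
#
# All windows are half-open intervals (randomization, randomization + h]
# measured in hours: 48 h ("within 2 days"), 72 h, 168 h ("7 days"),
# 672 h (28 days), 2160 h (90 days). No imputation is performed for missing
# data: unavailable quantities propagate as NA.

.CARE_2D_KINDS <- c("iv_fluids", "urinalysis", "fluid_io", "scr_measured",
                    "ultrasound", "nephrology_consult")
.NEPHROTOXINS <- c("contrast", "aminoglycoside", "vancomycin", "chemotherapy",
                   "nsaid", "acei_arb")
.EVENT_KINDS <- c("death", "dialysis_start", "hemoglobin", "aki_documented",
                  .CARE_2D_KINDS, .NEPHROTOXINS)

.in_window <- function(times, start, horizon) {
  times > start & times <= start + horizon
}

#' Primary outcome: maximum eGFR change within 7 days of randomization
#'
#' The maximum absolute change is the eGFR at AKI minus the lowest eGFR
#' observed at measurement times in the 7 days (168 h) after randomization.
#' If the patient dies within that window the eGFR is taken as 0. The maximum
#' relative change divides by the eGFR at randomization. eGFR at AKI and at
#' randomization are the same quantity here: randomization is triggered by
#' the AKI alert.
#'
#' @param series a [lab_series()] covering the admission.
#' @param demo a [demographics()] object.
#' @param randomization_time hours since admission.
#' @param death_time hours since admission, or `NA` if the patient did not
#'   die.
#' @return An object of class `primary_outcome` with fields
#'   `max_abs_egfr_change`, `max_rel_egfr_change`, `died_within_7d`,
#'   `egfr_at_aki`, `lowest_egfr_7d`. With no follow-up measurement and no
#'   death in the window, the change fields are `NA` (missing-value signal;
#'   no imputation is performed).
#' @export
primary_outcome <- function(series, demo, randomization_time, death_time = NA) {
  stopifnot(inherits(series, "lab_series"))
  scr0 <- .scr_at(series, randomization_time)
  if (is.na(scr0)) {
    stop("no creatinine available at randomization", call. = FALSE)
  }
  e0 <- egfr(scr0, demo$age, demo$sex)
  died7 <- !is.na(death_time) &&
    death_time > randomization_time && death_time <= randomization_time + 168
  keep <- .in_window(series$time, randomization_time, 168)
  if (!is.na(death_time)) keep <- keep & series$time <= death_time
  lowest <- if (any(keep)) {
    min(egfr(series$scr[keep], demo$age, demo$sex))
  } else NA_real_
  if (died7) lowest <- 0
  if (is.na(lowest)) {
    return(structure(list(max_abs_egfr_change = NA_real_,
                          max_rel_egfr_change = NA_real_,
                          died_within_7d = FALSE,
                          egfr_at_aki = e0, lowest_egfr_7d = NA_real_),
                     class = "primary_outcome"))
  }
  structure(
    list(max_abs_egfr_change = e0 - lowest,
         max_rel_egfr_change = (e0 - lowest) / e0,
         died_within_7d = died7,
         egfr_at_aki = e0,
         lowest_egfr_7d = lowest),
    class = "primary_outcome"
  )
}

#' Secondary patient-centered outcomes
#'
#' Windowed death and dialysis indicators, in-hospital AKI progression
#' (stage at randomization vs highest subsequent in-hospital stage), highest
#' stage achieved, recovery at discharge, and 90-day dialysis dependency.
#'
#' @param series a [lab_series()].
#' @param episode the patient's `aki_episode`.
#' @param events data frame with columns `kind`, `time` (hours since
#'   admission) and optional `value`; `death` and `dialysis_start` rows are
#'   used here.
#' @param demo a [demographics()] object (used by recovery bookkeeping).
#' @param randomization_time,discharge_time hours since admission.
#' @param dialysis_dependent_90d logical 90-day dialysis-dependency status
#'   from follow-up, or `NA` when 90-day status is unknown.
#' @param followup_90d logical: is 90-day vital status ascertained? When
#'   `FALSE` the 90-day fields are `NA` and all other fields are still
#'   computed.
#' @return A one-row data frame with logical/integer columns `death_7d`,
#'   `death_28d`, `death_90d`, `in_hospital_death`, `dialysis_7d`,
#'   `in_hospital_dialysis`, `aki_progression`, `stage_from`, `stage_to`,
#'   `highest_stage`, `recovery_at_discharge`, `alive_dialysis_dependent_90d`.
#' @export
secondary_outcomes <- function(series, episode, events, demo,
                               randomization_time, discharge_time,
                               dialysis_dependent_90d = NA,
                               followup_90d = TRUE) {
  stopifnot(inherits(series, "lab_series"), inherits(episode, "aki_episode"))
  death_time <- .first_event_time(events, "death")
  dialysis_time <- .first_event_time(events, "dialysis_start")
  r <- randomization_time

  death_7d <- !is.na(death_time) && .in_window(death_time, r, 168)
  death_28d <- !is.na(death_time) && .in_window(death_time, r, 672)
  death_90d <- !is.na(death_time) && .in_window(death_time, r, 2160)
  in_hospital_death <- !is.na(death_time) && death_time <= discharge_time
  dialysis_7d <- !is.na(dialysis_time) && .in_window(dialysis_time, r, 168)
  in_hospital_dialysis <- !is.na(dialysis_time) &&
    dialysis_time > r && dialysis_time <= discharge_time

  stage_rand <- stage_at(series, episode, r,
                         krt_started = !is.na(dialysis_time) && dialysis_time <= r)
  # highest stage strictly after randomization while still in hospital
  sub_times <- series$time[series$time > r & series$time <= discharge_time]
  stage_sub <- stage_rand
  if (!is.na(dialysis_time) && dialysis_time > r && dialysis_time <= discharge_time) {
    stage_sub <- 3L
  } else if (length(sub_times)) {
    stage_sub <- max(vapply(sub_times, function(t) {
      stage_at(series, episode, t,
               krt_started = !is.na(dialysis_time) && dialysis_time <= t)
    }, integer(1)))
  }
  # progression only ever records a strictly higher stage
  progressed <- stage_sub > stage_rand
  hi <- highest_stage(series, episode, min(discharge_time, max(series$time,
                                                               dialysis_time,
                                                               na.rm = TRUE)),
                      events = events)

  if (!followup_90d) {
    death_90d <- NA
    alive_dd_90 <- NA
  } else {
    alive_dd_90 <- if (is.na(dialysis_dependent_90d)) NA else {
      !death_90d && isTRUE(dialysis_dependent_90d)
    }
  }

  data.frame(
    death_7d = death_7d, death_28d = death_28d, death_90d = death_90d,
    in_hospital_death = in_hospital_death,
    dialysis_7d = dialysis_7d, in_hospital_dialysis = in_hospital_dialysis,
    aki_progression = progressed,
    stage_from = stage_rand,
    stage_to = if (progressed) stage_sub else NA_integer_,
    highest_stage = hi,
    recovery_at_discharge = recovery_at_discharge(series, episode,
                                                  discharge_time, events),
    alive_dialysis_dependent_90d = alive_dd_90
  )
}

.first_event_time <- function(events, what) {
  if (is.null(events) || !nrow(events)) return(NA_real_)
  tt <- events$time[events$kind == what]
  if (!length(tt)) NA_real_ else min(tt)
}

#' Care-centered process outcomes
#'
#' Flags diagnostic/therapeutic interventions within 2 days (48 h) of
#' randomization, nephrotoxin exposures within 3 and 7 days (72/168 h),
#' anemia correction (any hemoglobin strictly over 9.0 g/dL within 2 days),
#' and AKI documentation in the discharge record. Event kinds outside the
#' known vocabulary raise a warning and are ignored.
#'
#' @param events data frame with columns `kind`, `time` (hours since
#'   admission) and optional numeric `value` (used for `hemoglobin`).
#' @param randomization_time hours since admission.
#' @param discharge_time hours since admission (bounds `aki_documented` and
#'   length of stay).
#' @return A one-row data frame: `iv_fluids_2d`, `urinalysis_2d`,
#'   `fluid_io_2d`, `scr_measured_2d`, `ultrasound_2d`, `anemia_corrected_2d`,
#'   `nephrology_consult_2d`, `<toxin>_3d`/`<toxin>_7d` for the six
#'   nephrotoxin classes, `aki_documented`, `los_days`.
#' @export
care_outcomes <- function(events, randomization_time, discharge_time = Inf) {
  if (is.null(events)) events <- data.frame(kind = character(), time = numeric())
  unknown <- setdiff(unique(events$kind), .EVENT_KINDS)
  if (length(unknown)) {
    warning("ignoring unknown event kind(s): ", paste(unknown, collapse = ", "),
            call. = FALSE)
    events <- events[events$kind %in% .EVENT_KINDS, , drop = FALSE]
  }
  r <- randomization_time
  flag <- function(kind, horizon) {
    any(events$kind == kind & .in_window(events$time, r, horizon))
  }
  out <- list()
  for (k in .CARE_2D_KINDS) out[[paste0(k, "_2d")]] <- flag(k, 48)
  hb <- events$kind == "hemoglobin" & .in_window(events$time, r, 48)
  out$anemia_corrected_2d <- any(hb & !is.na(events$value) & events$value > 9.0)
  for (k in .NEPHROTOXINS) {
    out[[paste0(k, "_3d")]] <- flag(k, 72)
    out[[paste0(k, "_7d")]] <- flag(k, 168)
  }
  out$aki_documented <- any(events$kind == "aki_documented" &
                              events$time <= discharge_time)
  out$los_days <- if (is.finite(discharge_time)) discharge_time / 24 else NA_real_
  as.data.frame(out)
}

#' AKI recovery at discharge
#'
#' Default rule (the trial does not print its definition, so the rule is
#' explicit and configurable): the patient is alive at discharge, received no
#' in-hospital dialysis, and the last creatinine before discharge is below
#' `ratio_threshold` times the episode baseline.
#'
#' @param series a [lab_series()].
#' @param episode the `aki_episode`.
#' @param discharge_time hours since admission.
#' @param events event data frame (for `death` / `dialysis_start`).
#' @param ratio_threshold recovery ratio bound (default 1.5).
#' @return `TRUE`/`FALSE`, or `NA` when no discharge creatinine is available.
#' @export
recovery_at_discharge <- function(series, episode, discharge_time, events,
                                  ratio_threshold = 1.5) {
  death_time <- .first_event_time(events, "death")
  if (!is.na(death_time) && death_time <= discharge_time) return(FALSE)
  dialysis_time <- .first_event_time(events, "dialysis_start")
  if (!is.na(dialysis_time) && dialysis_time <= discharge_time) return(FALSE)
  last_scr <- .scr_at(series, discharge_time)
  if (is.na(last_scr)) return(NA)
  last_scr < ratio_threshold * episode$baseline_scr - .AKI_EPS
}
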
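# Delimited-table IO and end-to-end pipeline orchestration.
#
# File dialect: comma-separated, UTF-8, explicit header row, ISO-8601
# timestamps (UTC), empty string = missing. Creatinine is mg/dL internally;
# a labs `unit` column declaring "umol/L" is auto-converted (/ 88.4).

.TIME_FMT <- "%Y-%m-%dT%H:%M:%S"
UMOL_PER_MGDL <- 88.4

.fmt_time <- function(x) format(x, .TIME_FMT, tz = "UTC")

.parse_time <- function(x, file) {
  out <- as.POSIXct(x, format = .TIME_FMT, tz = "UTC")
  bad <- which(is.na(out) & !is.na(x) & nzchar(x))
  if (length(bad)) {
    stop(sprintf("unparseable timestamp in %s, line %d: '%s'",
                 file, bad[1] + 1L, x[bad[1]]), call. = FALSE)
  }
  out
}

.check_columns <- function(df, expected, file) {
  unknown <- setdiff(names(df), expected)
  if (length(unknown)) {
    stop(sprintf("unknown column(s) in %s: %s", file,
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  missing <- setdiff(expected, c(names(df), "unit"))
  if (length(missing)) {
    stop(sprintf("missing column(s) in %s: %s", file,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
}

#' Write a cohort to delimited tables
#'
#' Writes `admissions.csv`, `labs.csv`, `events.csv` and (when present)
#' `ground_truth.csv` into `dir`. Lab and event times are converted from
#' hours since admission to ISO-8601 timestamps.
#'
#' @param cohort a `synthetic_cohort` or the cohort list returned by
#'   [read_tables()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  adm <- cohort$admissions
  out_adm <- data.frame(
    patient_id = adm$patient_id,
    admit_time = .fmt_time(adm$admit_time),
    discharge_time = .fmt_time(adm$discharge_time),
    ward_type = adm$ward_type, icu = adm$icu, age = adm$age, sex = adm$sex,
    eskd_admission = adm$eskd_admission,
    kidney_transplant = adm$kidney_transplant,
    repeat_admission = adm$repeat_admission)
  utils::write.csv(out_adm, file.path(dir, "admissions.csv"),
                   row.names = FALSE, na = "")
  anchor <- adm$admit_time[match(cohort$labs$patient_id, adm$patient_id)]
  out_labs <- data.frame(
    patient_id = cohort$labs$patient_id,
    time = .fmt_time(anchor + cohort$labs$time * 3600),
    scr = cohort$labs$scr, unit = "mg/dL")
  utils::write.csv(out_labs, file.path(dir, "labs.csv"),
                   row.names = FALSE, na = "")
  ev <- cohort$events
  anchor <- adm$admit_time[match(ev$patient_id, adm$patient_id)]
  out_ev <- data.frame(
    patient_id = ev$patient_id,
    time = if (nrow(ev)) .fmt_time(anchor + ev$time * 3600) else character(),
    kind = ev$kind, value = ev$value)
  utils::write.csv(out_ev, file.path(dir, "events.csv"),
                   row.names = FALSE, na = "")
  if (!is.null(cohort$ground_truth)) {
    utils::write.csv(cohort$ground_truth, file.path(dir, "ground_truth.csv"),
                     row.names = FALSE, na = "")
  }
  invisible(dir)
}

#' Read cohort tables
#'
#' Reads `admissions.csv`, `labs.csv` and `events.csv` from `dir`, validates
#' the schemas (an unknown column is an error naming it), parses ISO-8601
#' timestamps (an unparseable one is an error with its line number), checks
#' referential integrity (every lab/event `patient_id` must appear in
#' admissions), and converts lab/event times to hours since the patient's
#' admission. Creatinine declared in umol/L is converted to mg/dL.
#'
#' @param dir directory containing the tables.
#' @return A cohort list with data frames `admissions`, `labs`, `events` and
#'   optionally `ground_truth`.
#' @export
read_tables <- function(dir) {
  read1 <- function(name) {
    path <- file.path(dir, name)
    if (!file.exists(path)) stop("missing input table: ", path, call. = FALSE)
    utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  }
  adm <- read1("admissions.csv")
  .check_columns(adm, c("patient_id", "admit_time", "discharge_time",
                        "ward_type", "icu", "age", "sex", "eskd_admission",
                        "kidney_transplant", "repeat_admission"),
                 "admissions.csv")
  adm$admit_time <- .parse_time(adm$admit_time, "admissions.csv")
  adm$discharge_time <- .parse_time(adm$discharge_time, "admissions.csv")
  if (any(adm$discharge_time <= adm$admit_time)) {
    stop("discharge_time must be after admit_time", call. = FALSE)
  }
  for (cl in c("icu", "eskd_admission", "kidney_transplant", "repeat_admission")) {
    adm[[cl]] <- as.logical(adm[[cl]])
  }

  labs <- read1("labs.csv")
  .check_columns(labs, c("patient_id", "time", "scr", "unit"), "labs.csv")
  orphans <- setdiff(labs$patient_id, adm$patient_id)
  if (length(orphans)) {
    stop("labs.csv references unknown patient id(s): ",
         paste(utils::head(orphans, 5), collapse = ", "), call. = FALSE)
  }
  labs_t <- .parse_time(labs$time, "labs.csv")
  labs$scr <- as.numeric(labs$scr)
  if ("unit" %in% names(labs)) {
    umol <- !is.na(labs$unit) & labs$unit %in% c("umol/L", "micromol/L")
    labs$scr[umol] <- labs$scr[umol] / UMOL_PER_MGDL
    labs$unit <- NULL
  }
  anchor <- adm$admit_time[match(labs$patient_id, adm$patient_id)]
  labs$time <- as.numeric(difftime(labs_t, anchor, units = "hours"))

  ev <- read1("events.csv")
  .check_columns(ev, c("patient_id", "time", "kind", "value"), "events.csv")
  orphans <- setdiff(ev$patient_id, adm$patient_id)
  if (length(orphans)) {
    stop("events.csv references unknown patient id(s): ",
         paste(utils::head(orphans, 5), collapse = ", "), call. = FALSE)
  }
  if (nrow(ev)) {
    ev_t <- .parse_time(ev$time, "events.csv")
    anchor <- adm$admit_time[match(ev$patient_id, adm$patient_id)]
    ev$time <- as.numeric(difftime(ev_t, anchor, units = "hours"))
    ev$value <- as.numeric(ev$value)
  } else {
    ev <- data.frame(patient_id = character(), time = numeric(),
                     kind = character(), value = numeric())
  }

  out <- list(admissions = adm, labs = labs, events = ev)
  gt_path <- file.path(dir, "ground_truth.csv")
  if (file.exists(gt_path)) {
    out$ground_truth <- utils::read.csv(gt_path, stringsAsFactors = FALSE,
                                        na.strings = "")
  }
  out
}

#' Pipeline configuration
#'
#' Collects every numeric constant of the detection, screening, outcome and
#' analysis stages with the trial's printed defaults: creatinine thresholds
#' 0.3 mg/dL and ratios 1.5/2.0/3.0, the 4.0 mg/dL stage-3 rule, eGFR
#' exclusion bound 15 mL/min/1.73 m^2, baseline creatinine bound 0.5 mg/dL,
#' windows of 48 h, 7 d, 2 d, 3 d, 28 d and 90 d, the 20180101 seed scheme,
#' the 3-message alert cap and the 95% confidence level.
#'
#' @param delta_threshold,ratio_threshold detection thresholds.
#' @param delta_window,baseline_window detection windows, hours.
#' @param scr4_rule stage-3 high-creatinine rule (see [stage_at()]).
#' @param egfr_exclusion,scr_exclusion,min_stay_hours eligibility bounds.
#' @param base_seed randomization seed scheme base.
#' @param allocation `"simple"` or `"blocks"`.
#' @param max_alerts alert cap per admission.
#' @param ci_level confidence level for the analysis tables.
#' @param recovery_ratio recovery-at-discharge ratio bound.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(delta_threshold = 0.3, ratio_threshold = 1.5,
                            delta_window = 48, baseline_window = 168,
                            scr4_rule = "value",
                            egfr_exclusion = 15, scr_exclusion = 0.5,
                            min_stay_hours = 24,
                            base_seed = 20180101,
                            allocation = "simple",
                            max_alerts = 3,
                            ci_level = 0.95,
                            recovery_ratio = 1.5) {
  vals <- as.list(environment())
  num <- vapply(vals, is.numeric, logical(1))
  if (any(unlist(vals[num]) <= 0)) {
    stop("all thresholds and windows must be positive", call. = FALSE)
  }
  structure(vals, class = "pipeline_config")
}

#' Write / read a pipeline configuration as YAML
#' @param config a [pipeline_config()].
#' @param path file path.
#' @return `read_config` returns a [pipeline_config()].
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

.admission_obj <- function(row) {
  admission(row$patient_id, row$age, row$sex, row$ward_type, row$icu,
            discharge_hours = as.numeric(difftime(row$discharge_time,
                                                  row$admit_time,
                                                  units = "hours")),
            eskd_admission = row$eskd_admission,
            kidney_transplant = row$kidney_transplant,
            repeat_admission = row$repeat_admission,
            admit_time = row$admit_time)
}

#' Run the full trial pipeline
#'
#' Detection -> eligibility screening -> stratified randomization -> alert
#' emission -> outcome derivation -> arm comparison, on a cohort object or a
#' directory of tables. Deterministic given the inputs and configuration.
#'
#' @param cohort a cohort list (from [generate_cohort()] or [read_tables()])
#'   or a directory path.
#' @param config a [pipeline_config()].
#' @param output_dir optional directory; when given, the assignments,
#'   outcomes, analysis tables, alert log and run log are written there.
#' @return A list with data frames `assignments`, `outcomes`, `results`, the
#'   alert `messages` (character vector) and the run `log`.
#' @export
run_pipeline <- function(cohort, config = pipeline_config(),
                         output_dir = NULL) {
  if (is.character(cohort)) cohort <- read_tables(cohort)
  stopifnot(inherits(config, "pipeline_config"))
  adm <- cohort$admissions
  if (is.null(adm) || nrow(adm) == 0) {
    stop("pipeline stage 'read': empty cohort (no admissions)", call. = FALSE)
  }
  log <- character()
  say <- function(...) log <<- c(log, sprintf(...))
  say("stage=detect admissions_in=%d", nrow(adm))

  labs_by <- split(cohort$labs, cohort$labs$patient_id)
  ev_by <- split(cohort$events, cohort$events$patient_id)

  det <- list()
  for (i in seq_len(nrow(adm))) {
    pid <- adm$patient_id[i]
    lb <- labs_by[[pid]]
    if (is.null(lb) || !nrow(lb)) next
    series <- lab_series(lb$time, lb$scr, adm$admit_time[i])
    ep <- detect_aki(series, delta_threshold = config$delta_threshold,
                     ratio_threshold = config$ratio_threshold,
                     delta_window = config$delta_window,
                     ratio_window = config$baseline_window,
                     scr4_rule = config$scr4_rule)
    if (!is.null(ep)) det[[pid]] <- list(row = i, series = series, episode = ep)
  }
  say("stage=screen episodes_detected=%d", length(det))

  # screening + enrolment order by absolute alert time
  screened <- lapply(names(det), function(pid) {
    d <- det[[pid]]
    a <- .admission_obj(adm[d$row, ])
    sc <- screen_eligibility(a, d$episode, d$series)
    list(pid = pid, adm = a, sc = sc,
         alert_abs = as.numeric(a$admit_time) + d$episode$onset_time * 3600,
         stratum = admission_stratum(a))
  })
  names(screened) <- names(det)
  ord <- order(vapply(screened, `[[`, numeric(1), "alert_abs"))
  screened <- screened[ord]

  # every alert is randomized at trigger time; exclusions are recorded and
  # applied afterwards (modified intention-to-treat)
  rows <- list()
  draw_counter <- stats::setNames(integer(length(STRATA)), STRATA)
  excl_tally <- integer(0)
  for (s in screened) {
    draw_counter[s$stratum] <- draw_counter[s$stratum] + 1L
    ra <- randomize(s$stratum, draw_counter[s$stratum],
                    base_seed = config$base_seed,
                    method = config$allocation)
    if (!s$sc$eligible) {
      excl_tally[s$sc$exclusion_reason] <-
        sum(excl_tally[s$sc$exclusion_reason], 1L, na.rm = TRUE)
    }
    rows[[s$pid]] <- data.frame(
      patient_id = s$pid, stratum = s$stratum, arm = ra$arm,
      seed_used = ra$seed_used, draw_index = ra$draw_index,
      exclusion_reason = s$sc$exclusion_reason, stringsAsFactors = FALSE)
  }
  assignments <- if (length(rows)) do.call(rbind, rows) else
    data.frame(patient_id = character(), stratum = character(),
               arm = character(), seed_used = integer(),
               draw_index = integer(), exclusion_reason = character())
  rownames(assignments) <- NULL
  for (r in names(excl_tally)) say("stage=screen excluded_%s=%d", r, excl_tally[r])
  say("stage=randomize randomized=%d mitt=%d", nrow(assignments),
      sum(is.na(assignments$exclusion_reason)))

  # alerts: one trigger per qualifying measurement, capped per admission
  messages <- character()
  for (pid in assignments$patient_id) {
    d <- det[[pid]]
    asg <- assignments[assignments$patient_id == pid, ]
    if (asg$arm != "alert") next
    trigger_times <- .qualifying_times(d$series, config)
    count <- 0L
    for (tt in trigger_times) {
      msg <- emit_alert(asg, d$episode, count, max_alerts = config$max_alerts)
      if (is.null(msg)) break
      count <- count + 1L
      messages <- c(messages, sprintf(
        "patient=%s seq=%d time_h=%.1f scr=%.2f", pid, msg$sequence_number,
        tt, .scr_at(d$series, tt)))
    }
  }
  say("stage=alert messages_sent=%d", length(messages))

  # outcomes for the modified intention-to-treat population: randomized
  # patients with none of the exclusion criteria
  out_rows <- list()
  for (pid in assignments$patient_id[is.na(assignments$exclusion_reason)]) {
    d <- det[[pid]]
    arow <- adm[adm$patient_id == pid, ]
    demo <- demographics(arow$age, arow$sex)
    ev <- ev_by[[pid]]
    if (is.null(ev)) ev <- data.frame(patient_id = character(),
                                      time = numeric(), kind = character(),
                                      value = numeric())
    rand_t <- d$episode$onset_time
    dis_t <- as.numeric(difftime(arow$discharge_time, arow$admit_time,
                                 units = "hours"))
    death_t <- .first_event_time(ev, "death")
    po <- primary_outcome(d$series, demo, rand_t, death_t)
    so <- secondary_outcomes(d$series, d$episode, ev, demo, rand_t, dis_t,
                             dialysis_dependent_90d = .dd90(ev, rand_t))
    ev_care <- ev
    if (!any(ev_care$kind == "scr_measured")) {
      # derive creatinine-measurement events from the lab stream
      extra <- data.frame(patient_id = pid,
                          time = d$series$time[d$series$time > rand_t],
                          kind = "scr_measured", value = NA_real_)
      ev_care <- rbind(ev_care, extra)
    }
    co <- care_outcomes(ev_care, rand_t, dis_t)
    out_rows[[pid]] <- cbind(
      data.frame(patient_id = pid,
                 arm = assignments$arm[assignments$patient_id == pid],
                 randomization_time = rand_t,
                 egfr_at_aki = po$egfr_at_aki,
                 lowest_egfr_7d = po$lowest_egfr_7d,
                 max_abs_egfr_change = po$max_abs_egfr_change,
                 max_rel_egfr_change = po$max_rel_egfr_change,
                 died_within_7d = po$died_within_7d,
                 stringsAsFactors = FALSE),
      so, co)
  }
  outcomes <- if (length(out_rows)) do.call(rbind, out_rows) else NULL
  if (!is.null(outcomes)) rownames(outcomes) <- NULL
  say("stage=outcomes patients=%d", if (is.null(outcomes)) 0L else nrow(outcomes))

  results <- if (!is.null(outcomes)) .analyze(outcomes, config$ci_level) else NULL
  say("stage=analyze rows=%d", if (is.null(results)) 0L else nrow(results))

  bundle <- list(assignments = assignments, outcomes = outcomes,
                 results = results, messages = messages, log = log)
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(assignments, file.path(output_dir, "assignments.csv"),
                     row.names = FALSE, na = "")
    if (!is.null(outcomes)) {
      utils::write.csv(outcomes, file.path(output_dir, "outcomes.csv"),
                       row.names = FALSE, na = "")
    }
    if (!is.null(results)) {
      utils::write.csv(results, file.path(output_dir, "results.csv"),
                       row.names = FALSE, na = "")
    }
    writeLines(messages, file.path(output_dir, "messages.log"))
    writeLines(log, file.path(output_dir, "run.log"))
  }
  bundle
}

.dd90 <- function(ev, rand_t) {
  # dialysis dependency at 90 days: a dialysis_start within the 90-day window
  # that is still the patient's latest kidney-replacement status
  dx <- .first_event_time(ev, "dialysis_start")
  if (is.na(dx)) FALSE else dx <= rand_t + 2160
}

.qualifying_times <- function(series, config) {
  hits <- c()
  for (i in seq_along(series$time)) {
    t <- series$time[i]; s <- series$scr[i]
    b48 <- rolling_min(series, t, config$delta_window)
    b7d <- rolling_min(series, t, config$baseline_window)
    if ((s - b48 >= config$delta_threshold - .AKI_EPS) ||
        (s >= config$ratio_threshold * b7d - .AKI_EPS && s > b7d)) {
      hits <- c(hits, t)
    }
  }
  hits
}

# arm comparison tables mirroring the trial's outcome tables
.analyze <- function(outcomes, ci_level = 0.95) {
  a <- outcomes[outcomes$arm == "alert", ]
  u <- outcomes[outcomes$arm == "usual_care", ]
  if (!nrow(a) || !nrow(u)) return(NULL)
  bin_row <- function(name, col) {
    xa <- a[[col]]; xu <- u[[col]]
    xa <- xa[!is.na(xa)]; xu <- xu[!is.na(xu)]
    if (!length(xa) || !length(xu)) return(NULL)
    rd <- risk_difference_ci(sum(xa), length(xa), sum(xu), length(xu),
                             level = ci_level)
    data.frame(outcome = name, type = "binary",
               n_usual = length(xu), usual = sum(xu),
               n_alert = length(xa), alert = sum(xa),
               difference = rd$difference, ci_low = rd$ci_low,
               ci_high = rd$ci_high, p_value = rd$p_value,
               stringsAsFactors = FALSE)
  }
  cont_row <- function(name, col) {
    xa <- a[[col]]; xu <- u[[col]]
    xa <- xa[!is.na(xa)]; xu <- xu[!is.na(xu)]
    if (length(xa) < 2 || length(xu) < 2) return(NULL)
    hl <- hodges_lehmann(xu, xa, level = ci_level)
    mw <- mann_whitney(xa, xu)
    data.frame(outcome = name, type = "continuous",
               n_usual = length(xu), usual = stats::median(xu),
               n_alert = length(xa), alert = stats::median(xa),
               difference = hl$estimate, ci_low = hl$ci_low,
               ci_high = hl$ci_high, p_value = mw$p_value,
               stringsAsFactors = FALSE)
  }
  bin_cols <- c("death_7d", "death_28d", "death_90d", "in_hospital_death",
                "dialysis_7d", "in_hospital_dialysis", "aki_progression",
                "recovery_at_discharge", "alive_dialysis_dependent_90d")
  care_cols <- grep("_(2d|3d|7d)$|^aki_documented$", names(outcomes),
                    value = TRUE)
  care_cols <- setdiff(care_cols, c(bin_cols, "died_within_7d",
                                    "lowest_egfr_7d"))
  rows <- c(
    list(cont_row("max_abs_egfr_change", "max_abs_egfr_change"),
         cont_row("max_rel_egfr_change", "max_rel_egfr_change"),
         cont_row("los_days", "los_days")),
    lapply(bin_cols, function(nm) bin_row(nm, nm)),
    lapply(care_cols, function(nm) bin_row(nm, nm))
  )
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  out
}
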
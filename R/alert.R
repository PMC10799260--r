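# Trial alert subsystem: eligibility screening against the exclusion list,
# stratified seeded 1:1 randomization, alert throttling, message rendering.

#' Randomization strata
#'
#' The four strata are the combinations of service type (medical vs surgical)
#' and location (ICU vs ward). Their order fixes the seed offsets used by
#' [randomize()].
#' @export
STRATA <- c("medical_icu", "medical_ward", "surgical_icu", "surgical_ward")

# exclusion reasons, in the order they are reported
.EXCLUSIONS <- c("baseline_egfr_lt_15", "eskd_admission", "kidney_transplant",
                 "community_acquired", "stay_lt_24h", "baseline_scr_lt_0.5",
                 "repeat_admission")

#' Describe one admission
#'
#' @param patient_id identifier.
#' @param age,sex demographics (see [demographics()]).
#' @param ward_type `"medical"` or `"surgical"`.
#' @param icu logical.
#' @param discharge_hours hours from admission to discharge.
#' @param eskd_admission logical: admission diagnosis of end-stage kidney
#'   disease.
#' @param kidney_transplant logical: history of kidney transplant.
#' @param repeat_admission logical: not the patient's first admission in the
#'   study period.
#' @param admit_time optional `POSIXct` anchor.
#' @return An object of class `admission`.
#' @export
admission <- function(patient_id, age, sex, ward_type = c("medical", "surgical"),
                      icu = FALSE, discharge_hours = Inf,
                      eskd_admission = FALSE, kidney_transplant = FALSE,
                      repeat_admission = FALSE, admit_time = NULL) {
  ward_type <- match.arg(ward_type)
  structure(
    list(patient_id = patient_id, age = age, sex = sex, ward_type = ward_type,
         icu = isTRUE(icu), discharge_hours = discharge_hours,
         eskd_admission = isTRUE(eskd_admission),
         kidney_transplant = isTRUE(kidney_transplant),
         repeat_admission = isTRUE(repeat_admission),
         admit_time = admit_time),
    class = "admission"
  )
}

#' Stratum of an admission
#' @param adm an [admission()].
#' @return One of [STRATA].
#' @export
admission_stratum <- function(adm) {
  paste(adm$ward_type, if (adm$icu) "icu" else "ward", sep = "_")
}

#' Screen a detected episode for trial eligibility
#'
#' Applies the trial's seven exclusion rules, in the order they are reported:
#' baseline eGFR < 15 mL/min/1.73 m^2, admission diagnosis of end-stage kidney
#' disease, kidney transplant history, community-acquired AKI, hospitalization
#' shorter than 24 h, baseline creatinine < 0.5 mg/dL, and repeat admission.
#' The decision is order-independent; when several rules apply the first in
#' this order is reported.
#'
#' Community-acquired AKI is operationalized as: the 7-day baseline window at
#' onset contains no in-admission measurement earlier than onset (the baseline
#' rests entirely on pre-admission values), or the criteria are already met at
#' the first in-admission measurement.
#'
#' @param adm an [admission()]; its `age`/`sex` must be present (the eGFR
#'   exclusion is otherwise uncomputable).
#' @param episode an `aki_episode` from [detect_aki()].
#' @param series the [lab_series()] the episode was detected on.
#' @return A list with `eligible` (logical) and `exclusion_reason` (`NA` or
#'   one of the seven reasons).
#' @export
screen_eligibility <- function(adm, episode, series) {
  stopifnot(inherits(adm, "admission"), inherits(episode, "aki_episode"),
            inherits(series, "lab_series"))
  if (is.null(adm$age) || is.null(adm$sex) || is.na(adm$age) || is.na(adm$sex)) {
    stop("demographics missing: baseline eGFR exclusion cannot be evaluated",
         call. = FALSE)
  }
  hits <- c(
    baseline_egfr_lt_15 = egfr(episode$baseline_scr, adm$age, adm$sex) < 15,
    eskd_admission = adm$eskd_admission,
    kidney_transplant = adm$kidney_transplant,
    community_acquired = .community_acquired(series, episode),
    stay_lt_24h = adm$discharge_hours < 24,
    `baseline_scr_lt_0.5` = episode$baseline_scr < 0.5,
    repeat_admission = adm$repeat_admission
  )
  if (any(hits)) {
    list(eligible = FALSE, exclusion_reason = .EXCLUSIONS[which(hits)[1L]])
  } else {
    list(eligible = TRUE, exclusion_reason = NA_character_)
  }
}

.community_acquired <- function(series, episode) {
  onset <- episode$onset_time
  if (onset < 0) return(TRUE)  # criteria met on pre-admission history alone
  # baseline window rests only on pre-admission history
  in_adm_before <- any(series$time >= 0 & series$time > onset - 168 &
                         series$time < onset)
  if (!in_adm_before && onset > 0) return(TRUE)
  # criteria already met at the first in-admission measurement
  first_in <- series$time[series$time >= 0]
  length(first_in) > 0 && abs(onset - first_in[1L]) < 1e-9 &&
    any(series$time < 0)
}

# run code without disturbing the caller's RNG stream
.with_preserved_seed <- function(expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  force(expr)
}

.arm_stream <- function(seed, n, method = c("simple", "blocks"), block_size = 4) {
  method <- match.arg(method)
  .with_preserved_seed({
    set.seed(seed, kind = "Mersenne-Twister")
    if (method == "simple") {
      ifelse(stats::runif(n) < 0.5, "alert", "usual_care")
    } else {
      stopifnot(block_size %% 2 == 0)
      nb <- ceiling(n / block_size)
      arms <- unlist(lapply(seq_len(nb), function(b) {
        sample(rep(c("alert", "usual_care"), block_size / 2))
      }))
      arms[seq_len(n)]
    }
  })
}

#' Stratified seeded 1:1 randomization
#'
#' Each stratum draws from its own reproducible stream: stratum `k` (0-based
#' index into [STRATA]) is seeded with `base_seed + k`, consecutive increments
#' of the universal seed 20180101. Draw `i` within a stratum is the `i`-th
#' value of that stream, so an assignment is fully determined by
#' `(stratum, draw_index)` independently of call order. The stream is R's
#' Mersenne-Twister; allocation is simple 1:1 Bernoulli by default, with
#' permuted blocks available.
#'
#' @param stratum one of [STRATA].
#' @param draw_index positive integer (vectorized): position of the patient in
#'   the stratum's enrolment sequence.
#' @param base_seed universal seed (default 20180101).
#' @param method `"simple"` (default) or `"blocks"`.
#' @param block_size even block size for `method = "blocks"`.
#' @return A data frame with columns `stratum`, `arm` (`"alert"` or
#'   `"usual_care"`), `seed_used` and `draw_index`.
#' @examples
#' randomize("medical_icu", 1:4)
#' @export
randomize <- function(stratum, draw_index, base_seed = 20180101,
                      method = c("simple", "blocks"), block_size = 4) {
  stratum <- match.arg(stratum, STRATA)
  method <- match.arg(method)
  draw_index <- as.integer(draw_index)
  stopifnot(all(draw_index >= 1L))
  seed <- base_seed + (match(stratum, STRATA) - 1L)
  arms <- .arm_stream(seed, max(draw_index), method, block_size)
  data.frame(stratum = stratum, arm = arms[draw_index],
             seed_used = seed, draw_index = draw_index,
             stringsAsFactors = FALSE)
}

# alert message template; bracketed tokens are filled by render_message()
.ALERT_TEMPLATE <- paste0(
  "Greetings, the patient in bed [bed], in the [ward] ward, admitted on ",
  "[admit_date], has a serum creatinine result of [scr] from the [test_date] ",
  "test time. Based on the creatinine result, acute kidney injury is probable ",
  "to occur. Acute kidney injury requires optimization of hemodynamics, ",
  "discontinuation of unnecessary nephrotoxic drugs, and adjustment of ",
  "antimicrobial drug dosage and dialysis if necessary. Please be vigilant ",
  "and handle it accordingly. Thank you! For diagnosis and treatment ",
  "inquiries, please contact the nephrology consultation service at the ",
  "kidney consultation phone number [phone].")

#' Render the alert message text
#'
#' Fills every bracketed placeholder of the alert template (bed, ward,
#' admission date, creatinine value, test date, consultation phone number).
#' Creatinine is formatted with two decimals in mg/dL.
#'
#' @param context named list with fields `bed`, `ward`, `admit_date`, `scr`
#'   (numeric, mg/dL), `test_date`, `phone`.
#' @return The rendered message string, free of residual bracket tokens.
#' @export
render_message <- function(context) {
  required <- c("bed", "ward", "admit_date", "scr", "test_date", "phone")
  missing <- setdiff(required, names(context))
  missing <- union(missing, required[vapply(
    required, function(f) f %in% names(context) &&
      (is.null(context[[f]]) || is.na(context[[f]])), logical(1))])
  if (length(missing)) {
    stop("missing message field(s): ", paste(sort(missing), collapse = ", "),
         call. = FALSE)
  }
  vals <- context
  vals$scr <- sprintf("%.2f", as.numeric(context$scr))
  out <- .ALERT_TEMPLATE
  for (f in required) {
    out <- sub(paste0("[", f, "]"), as.character(vals[[f]]), out, fixed = TRUE)
  }
  out
}

#' Emit a throttled alert message
#'
#' Produces an alert for the alert arm only, capped at 3 messages per
#' admission to limit alert fatigue; usual-care assignments and triggers past
#' the cap yield `NULL`.
#'
#' @param assignment a one-row assignment from [randomize()] (or any list with
#'   an `arm` element).
#' @param episode the triggering `aki_episode`.
#' @param prior_alert_count messages already sent for this admission.
#' @param context optional [render_message()] context; when supplied the
#'   rendered text is attached.
#' @param max_alerts message cap per admission (default 3).
#' @return An object of class `alert_message` (fields `scr_value`,
#'   `sequence_number`, `rendered_text`), or `NULL` when no message is sent.
#' @export
emit_alert <- function(assignment, episode, prior_alert_count,
                       context = NULL, max_alerts = 3) {
  arm <- if (is.list(assignment) || is.data.frame(assignment)) assignment$arm else assignment
  if (!identical(arm[1L], "alert")) return(NULL)
  if (prior_alert_count >= max_alerts) return(NULL)
  structure(
    list(scr_value = episode$scr_at_aki,
         sequence_number = as.integer(prior_alert_count + 1L),
         rendered_text = if (is.null(context)) NA_character_
                         else render_message(context)),
    class = "alert_message"
  )
}
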
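# KDIGO creatinine-criteria detection and staging over longitudinal
# serum-creatinine series, plus CKD-EPI eGFR.
#
# All creatinine values are mg/dL internally (multiply by 88.4 for umol/L);
# times are hours since admission (negative times are pre-admission history).

# numeric slack applied to every >=/< threshold comparison so that values that
# are exactly on a printed threshold (0.3, 1.5x, ...) behave as the criteria
# read despite binary floating point
.AKI_EPS <- 1e-9

#' Build a laboratory creatinine series
#'
#' A `lab_series` holds the timestamped serum-creatinine measurements for one
#' admission, ordered by time. Times are hours since admission; negative times
#' represent pre-admission history measurements that are still eligible as
#' 7-day baseline comparators.
#'
#' @param time numeric vector, hours since admission (need not be equally
#'   spaced; sorted internally).
#' @param scr numeric vector of serum creatinine values, mg/dL; must be
#'   strictly positive.
#' @param admission_time optional `POSIXct` anchor for the admission.
#' @return An object of class `lab_series` with elements `time`, `scr` and
#'   `admission_time`.
#' @examples
#' s <- lab_series(c(0, 24, 60), c(1.0, 0.8, 1.3))
#' rolling_min(s, t = 60, window = 168)
#' @export
lab_series <- function(time, scr, admission_time = NULL) {
  if (length(time) != length(scr)) {
    stop("`time` and `scr` must have the same length", call. = FALSE)
  }
  if (length(time) < 1L) stop("a lab series needs at least one measurement", call. = FALSE)
  if (any(!is.finite(time)) || any(!is.finite(scr))) {
    stop("times and creatinine values must be finite", call. = FALSE)
  }
  if (any(scr <= 0)) stop("serum creatinine must be positive (mg/dL)", call. = FALSE)
  o <- order(time)
  structure(
    list(time = as.numeric(time[o]), scr = as.numeric(scr[o]),
         admission_time = admission_time),
    class = "lab_series"
  )
}

#' @export
print.lab_series <- function(x, ...) {
  cat(sprintf("<lab_series> %d measurements, %.1f to %.1f h, SCr %.2f-%.2f mg/dL\n",
              length(x$time), min(x$time), max(x$time), min(x$scr), max(x$scr)))
  invisible(x)
}

#' Rolling minimum creatinine over a trailing window
#'
#' Minimum creatinine among measurements with time in the half-open interval
#' `(t - window, t]`. A measurement exactly `window` hours before `t` is
#' excluded; the measurement at `t` itself (if any) is included — it can never
#' trigger a criterion against itself because its rise over itself is zero.
#'
#' @param series a [lab_series()].
#' @param t evaluation time, hours since admission.
#' @param window trailing window width in hours (48 for the absolute-rise
#'   criterion, 168 for the 7-day baseline).
#' @return The minimum creatinine in the window (mg/dL), or `NA_real_` when
#'   the window contains no measurement.
#' @export
rolling_min <- function(series, t, window) {
  stopifnot(inherits(series, "lab_series"), window > 0)
  keep <- series$time > t - window & series$time <= t
  if (!any(keep)) return(NA_real_)
  min(series$scr[keep])
}

# creatinine value in effect at time t: most recent measurement at or before t
.scr_at <- function(series, t) {
  i <- findInterval(t + .AKI_EPS, series$time)
  if (i < 1L) return(NA_real_)
  series$scr[i]
}

#' Detect an AKI episode by the KDIGO creatinine criteria
#'
#' Scans the series in time order and returns the earliest measurement time at
#' which either creatinine criterion holds:
#' * absolute rise: `scr(t) - min scr in (t-48h, t] >= 0.3` mg/dL, or
#' * relative rise: `scr(t) >= 1.5 x` the lowest creatinine in the previous
#'   7 days `(t-168h, t]`.
#'
#' The episode baseline is the 7-day rolling minimum at onset, frozen for the
#' episode and reused by all staging ratios. When both criteria hold at the
#' same measurement the recorded criterion is the absolute-rise one
#' (reporting-only tie-break; the onset time is unaffected).
#'
#' @param series a [lab_series()].
#' @param demo optional [demographics()]; when supplied, `egfr_at_aki` is
#'   filled using [egfr()].
#' @param delta_threshold absolute-rise threshold, mg/dL (default 0.3).
#' @param ratio_threshold relative-rise threshold (default 1.5).
#' @param delta_window,ratio_window trailing windows in hours (defaults 48 and
#'   168).
#' @param scr4_rule stage-3 high-creatinine rule passed to [stage_at()].
#' @return An object of class `aki_episode` (fields `onset_time`, `criterion`
#'   = `"delta048"` or `"ratio7d"`, `baseline_scr`, `scr_at_aki`,
#'   `egfr_at_aki`, `stage_at_onset`), or `NULL` when neither criterion is
#'   ever met.
#' @examples
#' detect_aki(lab_series(c(0, 36), c(0.8, 1.1)))  # 0.3 mg/dL rise in 48 h
#' @export
detect_aki <- function(series, demo = NULL,
                       delta_threshold = 0.3, ratio_threshold = 1.5,
                       delta_window = 48, ratio_window = 168,
                       scr4_rule = c("value", "increase")) {
  stopifnot(inherits(series, "lab_series"))
  scr4_rule <- match.arg(scr4_rule)
  for (i in seq_along(series$time)) {
    t <- series$time[i]
    s <- series$scr[i]
    b48 <- rolling_min(series, t, delta_window)
    b7d <- rolling_min(series, t, ratio_window)
    hit_delta <- !is.na(b48) && (s - b48 >= delta_threshold - .AKI_EPS)
    hit_ratio <- !is.na(b7d) && (s >= ratio_threshold * b7d - .AKI_EPS) && s > b7d
    if (hit_delta || hit_ratio) {
      ep <- structure(
        list(onset_time = t,
             criterion = if (hit_delta) "delta048" else "ratio7d",
             baseline_scr = b7d,
             scr_at_aki = s,
             egfr_at_aki = NA_real_,
             stage_at_onset = NA_integer_),
        class = "aki_episode"
      )
      ep$stage_at_onset <- stage_at(series, ep, t, scr4_rule = scr4_rule)
      if (!is.null(demo)) ep$egfr_at_aki <- egfr(s, demo$age, demo$sex)
      return(ep)
    }
  }
  NULL
}

#' @export
print.aki_episode <- function(x, ...) {
  cat(sprintf(
    "<aki_episode> onset %.1f h (%s), baseline %.2f -> %.2f mg/dL, stage %d at onset\n",
    x$onset_time, x$criterion, x$baseline_scr, x$scr_at_aki, x$stage_at_onset))
  invisible(x)
}

#' KDIGO stage at a time point
#'
#' Stage of an established episode at time `t`, from the creatinine in effect
#' at `t` (most recent measurement at or before `t`) relative to the episode's
#' frozen baseline:
#' * stage 3: kidney replacement therapy started, or ratio >= 3.0, or the
#'   high-creatinine rule (see `scr4_rule`);
#' * stage 2: ratio in `[2.0, 3.0)`;
#' * stage 1: otherwise (the episode already satisfies a stage-1 criterion).
#'
#' @param series a [lab_series()].
#' @param episode an `aki_episode` from [detect_aki()].
#' @param t evaluation time in hours; must be at or after onset.
#' @param krt_started logical; `TRUE` once kidney replacement therapy
#'   (dialysis) has been initiated at or before `t`.
#' @param scr4_rule `"value"` (default): stage 3 when the creatinine value is
#'   >= 4.0 mg/dL in a patient already meeting AKI criteria — standard KDIGO
#'   semantics; `"increase"`: stage 3 when the rise over baseline is >= 4.0
#'   mg/dL, a stricter literal reading.
#' @return Integer stage 1, 2 or 3.
#' @export
stage_at <- function(series, episode, t, krt_started = FALSE,
                     scr4_rule = c("value", "increase")) {
  stopifnot(inherits(series, "lab_series"), inherits(episode, "aki_episode"))
  scr4_rule <- match.arg(scr4_rule)
  if (t < episode$onset_time - .AKI_EPS) {
    stop("stage_at() requires t at or after episode onset", call. = FALSE)
  }
  s <- .scr_at(series, t)
  ratio <- s / episode$baseline_scr
  scr4_hit <- switch(scr4_rule,
    value = s >= 4.0 - .AKI_EPS,
    increase = s - episode$baseline_scr >= 4.0 - .AKI_EPS
  )
  if (isTRUE(krt_started) || ratio >= 3.0 - .AKI_EPS || scr4_hit) return(3L)
  if (ratio >= 2.0 - .AKI_EPS) return(2L)
  1L
}

#' Highest KDIGO stage achieved over a horizon
#'
#' Maximum of [stage_at()] over all measurement times in `[onset, horizon]`.
#' Initiation of kidney replacement therapy at any time up to `horizon`
#' (a `dialysis_start` entry in `events`) forces stage 3.
#'
#' @param series a [lab_series()].
#' @param episode an `aki_episode`.
#' @param horizon end of the evaluation window, hours since admission.
#' @param events optional data frame with columns `kind` and `time` (hours);
#'   only `dialysis_start` rows are used here.
#' @param scr4_rule see [stage_at()].
#' @return Integer stage 1, 2 or 3.
#' @export
highest_stage <- function(series, episode, horizon, events = NULL,
                          scr4_rule = c("value", "increase")) {
  scr4_rule <- match.arg(scr4_rule)
  krt_time <- Inf
  if (!is.null(events) && nrow(events)) {
    dt <- events$time[events$kind == "dialysis_start"]
    if (length(dt)) krt_time <- min(dt)
  }
  if (krt_time <= horizon) return(3L)
  times <- series$time[series$time >= episode$onset_time - .AKI_EPS &
                         series$time <= horizon + .AKI_EPS]
  if (!length(times)) times <- episode$onset_time
  max(vapply(times, function(t) {
    stage_at(series, episode, t, krt_started = t >= krt_time, scr4_rule = scr4_rule)
  }, integer(1)))
}

#' Patient demographics for eGFR
#'
#' @param age age in years; the trial enrolled adults, so `age >= 18`.
#' @param sex `"male"` or `"female"`.
#' @return An object of class `demographics`.
#' @export
demographics <- function(age, sex = c("male", "female")) {
  sex <- match.arg(sex)
  if (!is.finite(age) || age < 18) stop("age must be >= 18 years", call. = FALSE)
  structure(list(age = as.numeric(age), sex = sex), class = "demographics")
}

#' CKD-EPI estimated glomerular filtration rate
#'
#' Estimated GFR in mL/min/1.73 m^2 from serum creatinine, age and sex. The
#' default is the 2009 CKD-EPI creatinine equation without the race
#' coefficient:
#' `eGFR = 141 x min(SCr/k, 1)^a x max(SCr/k, 1)^-1.209 x 0.993^age x 1.018[female]`
#' with `k = 0.7` (female) / `0.9` (male) and `a = -0.329` / `-0.411`.
#' The race-coefficient 2009 variant (x1.159) and the 2021 refit are available
#' behind `variant`.
#'
#' @param scr serum creatinine, mg/dL (vectorized; must be positive).
#' @param age age in years (>= 18).
#' @param sex `"male"` or `"female"` (recycled).
#' @param variant `"ckdepi2009"` (default), `"ckdepi2009_race"` or
#'   `"ckdepi2021"`.
#' @param black logical, used only by the race variant.
#' @return eGFR in mL/min/1.73 m^2, strictly decreasing in `scr` and in `age`.
#' @examples
#' egfr(1.0, 60, "male")
#' @export
egfr <- function(scr, age, sex,
                 variant = c("ckdepi2009", "ckdepi2009_race", "ckdepi2021"),
                 black = FALSE) {
  variant <- match.arg(variant)
  if (any(!is.finite(scr)) || any(scr <= 0)) {
    stop("serum creatinine must be positive", call. = FALSE)
  }
  if (any(age < 18)) stop("age must be >= 18 years", call. = FALSE)
  n <- max(length(scr), length(age), length(sex))
  scr <- rep_len(scr, n); age <- rep_len(age, n); sex <- rep_len(sex, n)
  if (!all(sex %in% c("male", "female"))) {
    stop('sex must be "male" or "female"', call. = FALSE)
  }
  female <- sex == "female"
  if (variant == "ckdepi2021") {
    kappa <- ifelse(female, 0.7, 0.9)
    alpha <- ifelse(female, -0.241, -0.302)
    g <- 142 * pmin(scr / kappa, 1)^alpha * pmax(scr / kappa, 1)^-1.200 *
      0.9938^age
    g[female] <- g[female] * 1.012
  } else {
    kappa <- ifelse(female, 0.7, 0.9)
    alpha <- ifelse(female, -0.329, -0.411)
    g <- 141 * pmin(scr / kappa, 1)^alpha * pmax(scr / kappa, 1)^-1.209 *
      0.993^age
    g[female] <- g[female] * 1.018
    if (variant == "ckdepi2009_race" && isTRUE(black)) g <- g * 1.159
  }
  g
}
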